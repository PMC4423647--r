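# SBML Level 2/3 core reader. The document is parsed into a
# format-neutral in-memory model: ListOfX containers are dissolved (their
# children attach directly to the parent), XML attributes are copied
# verbatim (with a typed view alongside the source lexical form), and
# controlled-vocabulary annotations are flattened out of their rdf:Bag
# containers into (qualifier, resource URI) pairs.

.SBML_NS_L2 <- "http://www.sbml.org/sbml/level2"
.SBML_NS_L3 <- "http://www.sbml.org/sbml/level3"

# attribute typing: decimals and booleans needed for literal datatypes
# downstream; everything else stays a string
.DECIMAL_ATTRS <- c("initialAmount", "initialConcentration", "size", "stoichiometry")
.BOOLEAN_ATTRS <- c("reversible", "constant", "boundaryCondition")

log_note <- function(...) message("sbml2rdf: ", ...)

#' Parse an SBML document
#'
#' Reads an SBML Level 2 or Level 3 (core) file into an [sbml_model]:
#' compartments, species, reactions (with their reactant/product/
#' modifier species references), parameters, unit definitions and rules,
#' in document order. `ListOfX` grouping elements are dissolved.
#' XHTML notes are flattened to plain text; kinetic-law and rule math is
#' kept as MathML source for string rendering (see [convert_math()]).
#' Constructs from SBML Level 3 packages are skipped with a warning.
#'
#' @param source file path, raw vector, or single character string of
#'   XML.
#' @return An [sbml_model].
#' @examples
#' model <- parse_sbml(paper_fragment())
#' length(model$species)
#' @export
parse_sbml <- function(source) {
  doc <- tryCatch(
    xml2::read_xml(source),
    error = function(e) stop("SBML parse error: ", conditionMessage(e), call. = FALSE)
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml") {
    stop("unsupported format: root element is <", xml2::xml_name(root),
      ">, not <sbml>", call. = FALSE)
  }
  level <- suppressWarnings(as.integer(xml2::xml_attr(root, "level")))
  if (is.na(level) || !level %in% c(2L, 3L)) {
    stop("unsupported SBML level: ",
      if (is.na(level)) "missing level attribute" else level,
      " (only Level 2 and Level 3 core are supported)", call. = FALSE)
  }
  version <- suppressWarnings(as.integer(xml2::xml_attr(root, "version")))
  model_node <- xml2::xml_find_first(root, "./*[local-name()='model']")
  if (inherits(model_node, "xml_missing")) {
    stop("SBML document contains no <model> element", call. = FALSE)
  }
  model_id <- xml2::xml_attr(model_node, "id")
  if (is.na(model_id) || !nzchar(model_id)) {
    stop("model has no id attribute; a non-empty model id is required for URI minting",
      call. = FALSE)
  }

  nsmap <- xml2::xml_ns(doc)
  model <- list(
    model_id = model_id,
    name = attr_or_null(model_node, "name"),
    metaid = attr_or_null(model_node, "metaid"),
    level = level,
    version = version,
    notes_text = parse_notes(model_node),
    annotations = parse_annotation_node(model_node, nsmap),
    compartments = list(), species = list(), reactions = list(),
    parameters = list(), unit_definitions = list(), rules = list()
  )

  for (child in as.list(xml2::xml_children(model_node))) {
    nm <- xml2::xml_name(child)
    items <- as.list(xml2::xml_children(child))
    switch(nm,
      listOfCompartments = {
        model$compartments <- parse_kind(items, "compartment", nsmap)
      },
      listOfSpecies = {
        model$species <- parse_kind(items, "species", nsmap)
      },
      listOfReactions = {
        model$reactions <- lapply(items, parse_reaction, nsmap = nsmap)
      },
      listOfParameters = {
        model$parameters <- parse_kind(items, "parameter", nsmap)
      },
      listOfUnitDefinitions = {
        model$unit_definitions <- parse_kind(items, "unit_definition", nsmap)
      },
      listOfRules = {
        model$rules <- lapply(items, parse_rule, nsmap = nsmap)
      },
      notes = NULL, annotation = NULL,
      {
        ns_uri <- node_ns_uri(child, nsmap)
        if (!is.na(ns_uri) && !grepl("sbml.org/sbml/level[23]", ns_uri)) {
          warning("skipping SBML package construct <", nm, "> (", ns_uri, ")",
            call. = FALSE)
        } else if (!nm %in% c("listOfFunctionDefinitions", "listOfInitialAssignments",
            "listOfConstraints", "listOfEvents", "listOfCompartmentTypes",
            "listOfSpeciesTypes")) {
          log_note("ignoring model child <", nm, ">")
        }
      }
    )
  }
  structure(model, class = "sbml_model")
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf(
    "<sbml_model %s (L%dV%d)%s>\n  compartments: %d  species: %d  reactions: %d\n  parameters: %d  unit definitions: %d  rules: %d  annotations: %d\n",
    x$model_id, x$level, x$version,
    if (!is.null(x$name)) paste0(" '", x$name, "'") else "",
    length(x$compartments), length(x$species), length(x$reactions),
    length(x$parameters), length(x$unit_definitions), length(x$rules),
    nrow(x$annotations)
  ))
  invisible(x)
}

attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

node_ns_uri <- function(node, nsmap) {
  q <- xml2::xml_name(node, ns = nsmap)
  if (!grepl(":", q, fixed = TRUE)) return(NA_character_)
  prefix <- sub(":.*$", "", q)
  unname(nsmap[[prefix]])
}

parse_kind <- function(nodes, kind, nsmap) {
  lapply(nodes, parse_element, kind = kind, nsmap = nsmap)
}

new_sbml_element <- function(kind, sbml_id = NULL, metaid = NULL, name = NULL,
                             attributes = list(), attributes_raw = character(),
                             annotations = annotation_links(), notes_text = NULL,
                             children = list(), species = NULL, math = NULL) {
  structure(
    list(kind = kind, sbml_id = sbml_id, metaid = metaid, name = name,
      attributes = attributes, attributes_raw = attributes_raw,
      annotations = annotations, notes_text = notes_text,
      children = children, species = species, math = math),
    class = "sbml_element"
  )
}

#' @export
print.sbml_element <- function(x, ...) {
  cat(sprintf("<sbml_element %s%s%s: %d attrs, %d annotations>\n", x$kind,
    if (!is.null(x$sbml_id)) paste0(" id=", x$sbml_id) else "",
    if (!is.null(x$metaid)) paste0(" metaid=", x$metaid) else "",
    length(x$attributes), nrow(x$annotations)))
  invisible(x)
}

# Attributes present in the source XML, minus the ones held in dedicated
# fields. Returns list(typed = named list, raw = named character).
parse_attributes <- function(node, drop = c("id", "metaid", "name")) {
  attrs <- xml2::xml_attrs(node)
  attrs <- attrs[!names(attrs) %in% drop]
  attrs <- attrs[!grepl(":", names(attrs), fixed = TRUE)]
  typed <- lapply(seq_along(attrs), function(i) {
    nm <- names(attrs)[i]
    v <- attrs[[i]]
    if (nm %in% .DECIMAL_ATTRS) {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    } else if (nm %in% .BOOLEAN_ATTRS) {
      if (v %in% c("true", "1")) TRUE
      else if (v %in% c("false", "0")) FALSE
      else v
    } else {
      v
    }
  })
  names(typed) <- names(attrs)
  list(typed = typed, raw = attrs)
}

parse_element <- function(node, kind, nsmap, drop = c("id", "metaid", "name")) {
  at <- parse_attributes(node, drop)
  new_sbml_element(
    kind = kind,
    sbml_id = attr_or_null(node, "id"),
    metaid = attr_or_null(node, "metaid"),
    name = attr_or_null(node, "name"),
    attributes = at$typed,
    attributes_raw = at$raw,
    annotations = parse_annotation_node(node, nsmap),
    notes_text = parse_notes(node)
  )
}

parse_reaction <- function(node, nsmap) {
  el <- parse_element(node, "reaction", nsmap)
  refs <- list(reactants = list(), products = list(), modifiers = list())
  for (child in as.list(xml2::xml_children(node))) {
    nm <- xml2::xml_name(child)
    role <- switch(nm,
      listOfReactants = "reactants",
      listOfProducts = "products",
      listOfModifiers = "modifiers",
      NULL
    )
    if (!is.null(role)) {
      refs[[role]] <- lapply(as.list(xml2::xml_children(child)),
        parse_species_reference, nsmap = nsmap)
    } else if (nm == "kineticLaw") {
      math <- xml2::xml_find_first(child, "./*[local-name()='math']")
      if (!inherits(math, "xml_missing")) el$math <- as.character(math)
    }
  }
  el$children <- refs
  el
}

parse_species_reference <- function(node, nsmap) {
  species <- attr_or_null(node, "species")
  if (is.null(species)) {
    stop("speciesReference without a species attribute", call. = FALSE)
  }
  el <- parse_element(node, "species_reference", nsmap,
    drop = c("id", "metaid", "name", "species"))
  el$species <- species
  el
}

parse_rule <- function(node, nsmap) {
  el <- parse_element(node, "rule", nsmap)
  el$rule_type <- xml2::xml_name(node)
  math <- xml2::xml_find_first(node, "./*[local-name()='math']")
  if (!inherits(math, "xml_missing")) el$math <- as.character(math)
  el
}

parse_notes <- function(node) {
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  if (inherits(notes, "xml_missing")) return(NULL)
  flatten_text(xml2::xml_text(notes))
}

flatten_text <- function(x) {
  out <- trimws(gsub("[ \t\r\n]+", " ", x))
  if (nzchar(out)) out else NULL
}

parse_annotation_node <- function(node, nsmap) {
  ann <- xml2::xml_find_first(node, "./*[local-name()='annotation']")
  if (inherits(ann, "xml_missing")) return(annotation_links())
  extract_annotations(ann, nsmap)
}

#' Empty (or explicit) annotation-link collection
#'
#' Annotation links are `(qualifier, resource URI)` pairs in a
#' data.frame with columns `ns` (qualifier namespace tag, normally
#' `"bqbiol"` or `"bqmodel"`), `local` (qualifier local name) and `uri`
#' (the cross-referenced resource).
#'
#' @param ns,local,uri equal-length character vectors.
#' @return data.frame of annotation links.
#' @export
annotation_links <- function(ns = character(), local = character(),
                             uri = character()) {
  data.frame(ns = as.character(ns), local = as.character(local),
    uri = as.character(uri), stringsAsFactors = FALSE)
}

qualifier_tag_for_ns <- function(ns_uri) {
  if (is.na(ns_uri)) return(NA_character_)
  base <- sub("[/#]$", "", ns_uri)
  if (base == .NS_BQBIOL_BASE) "bqbiol"
  else if (base == .NS_BQMODEL_BASE) "bqmodel"
  else NA_character_
}

#' Flatten the controlled-vocabulary annotations of an SBML element
#'
#' Walks the RDF block inside an SBML `annotation` element and returns
#' one link per `rdf:li` resource found under each qualifier's
#' `rdf:Bag`, in document order; the bag scaffolding itself is
#' discarded. Qualifiers from namespaces other than the BioModels
#' biology/model qualifiers are retained with their namespace URI
#' recorded verbatim as the tag, and flagged in the log.
#'
#' @param annotation_xml an `xml2` node for the `annotation` element (or
#'   any element containing `rdf:RDF`), or a string of XML.
#' @param nsmap namespace map of the containing document; derived
#'   automatically when `annotation_xml` is a string.
#' @return data.frame of annotation links (see [annotation_links()]).
#' @examples
#' xml <- paste0(
#'   '<annotation><rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
#'   ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
#'   '<rdf:Description rdf:about="#meta1"><bqbiol:is><rdf:Bag>',
#'   '<rdf:li rdf:resource="http://identifiers.org/taxonomy/10114"/>',
#'   '</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>')
#' extract_annotations(xml)
#' @export
extract_annotations <- function(annotation_xml, nsmap = NULL) {
  if (is.character(annotation_xml)) {
    annotation_xml <- xml2::xml_root(xml2::read_xml(annotation_xml))
  }
  if (is.null(nsmap)) nsmap <- xml2::xml_ns(annotation_xml)
  descriptions <- xml2::xml_find_all(annotation_xml,
    ".//*[local-name()='RDF' and namespace-uri()='http://www.w3.org/1999/02/22-rdf-syntax-ns#']/*[local-name()='Description']")
  if (!length(descriptions)) return(annotation_links())

  ns <- character(); local <- character(); uri <- character()
  for (desc in as.list(descriptions)) {
    for (qual in as.list(xml2::xml_children(desc))) {
      qname <- xml2::xml_name(qual)
      ns_uri <- node_ns_uri(qual, nsmap)
      tag <- qualifier_tag_for_ns(ns_uri)
      if (is.na(tag)) {
        tag <- if (is.na(ns_uri)) "" else ns_uri
        log_note("qualifier '", qname, "' from unrecognized namespace '",
          tag, "' retained")
      }
      resources <- annotation_resources(qual)
      if (length(resources)) {
        ns <- c(ns, rep(tag, length(resources)))
        local <- c(local, rep(qname, length(resources)))
        uri <- c(uri, resources)
      }
    }
  }
  annotation_links(ns, local, uri)
}

# rdf:resource URIs under one qualifier element: every rdf:li in document
# order (the usual rdf:Bag form), plus a direct rdf:resource attribute
# for bag-less annotations.
annotation_resources <- function(qual) {
  out <- character()
  direct <- xml2::xml_attr(qual, "resource")
  if (!is.na(direct)) out <- c(out, direct)
  lis <- xml2::xml_find_all(qual,
    ".//*[local-name()='li' and namespace-uri()='http://www.w3.org/1999/02/22-rdf-syntax-ns#']")
  res <- vapply(as.list(lis), function(li) {
    v <- xml2::xml_attr(li, "resource")
    if (is.na(v)) NA_character_ else v
  }, character(1))
  out <- c(out, res[!is.na(res)])
  out[grepl("^[A-Za-z][A-Za-z0-9+.-]*:", out)]
}
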
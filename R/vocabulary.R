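#' Prefix-to-namespace table of the conversion vocabulary
#'
#' Returns the namespace table used throughout the conversion: the four
#' BioModels prefixes (`biodb`, `sbmlrdf`, `bqbiol`, `bqmodel`) plus the
#' standard `rdf`, `rdfs`, `owl` and `xsd` namespaces. The `sbmlrdf`
#' vocabulary terms live behind a `#` separator and the qualifier
#' namespaces behind a `/`; both separators can be overridden for
#' installations that minted their URIs differently.
#'
#' @param sbmlrdf_sep separator appended to the vocabulary namespace
#'   (default `"#"`).
#' @param qualifier_sep separator appended to the two qualifier
#'   namespaces (default `"/"`).
#' @return Named character vector mapping prefix to namespace URI.
#' @examples
#' ns_table()[["biodb"]]
#' @export
ns_table <- function(sbmlrdf_sep = "#", qualifier_sep = "/") {
  c(
    biodb = .NS_BIODB,
    sbmlrdf = paste0(.NS_SBMLRDF_BASE, sbmlrdf_sep),
    bqbiol = paste0(.NS_BQBIOL_BASE, qualifier_sep),
    bqmodel = paste0(.NS_BQMODEL_BASE, qualifier_sep),
    rdf = .NS_RDF,
    rdfs = .NS_RDFS,
    owl = .NS_OWL,
    xsd = .NS_XSD
  )
}

sbmlrdf_uri <- function(local) paste0(.NS_SBMLRDF_BASE, "#", local)

# Element-kind enum shared by the parser, vocabulary and converter.
.SBML_KINDS <- c(
  "compartment", "species", "reaction", "species_reference",
  "parameter", "unit_definition", "rule"
)

# kind -> RDF class local name
.CLASS_LOCAL <- c(
  model = "SBMLModel",
  compartment = "Compartment",
  species = "Species",
  reaction = "Reaction",
  species_reference = "SpeciesReference",
  parameter = "Parameter",
  unit_definition = "UnitDefinition",
  rule = "Rule"
)

# kind -> membership property linking a model to its top-level elements
.MEMBER_PROP <- c(
  compartment = "compartment",
  species = "species",
  reaction = "reaction",
  parameter = "parameter",
  unit_definition = "unitDefinition",
  rule = "rule"
)

# Known attribute- and relation-derived property local names.
.KNOWN_PROPERTIES <- c(
  "name", "id", "notes", "curated",
  "initialAmount", "initialConcentration", "substanceUnits",
  "hasOnlySubstanceUnits", "boundaryCondition", "constant",
  "compartment", "size", "spatialDimensions", "units", "volume",
  "reversible", "fast", "stoichiometry", "value", "variable",
  "species", "reaction", "parameter", "unitDefinition", "rule",
  "reactant", "product", "modifier",
  "conversionFactor", "timeUnits", "extentUnits", "areaUnits",
  "lengthUnits", "volumeUnits", "charge", "metaidRef", "sboTerm"
)

new_vocab_term <- function(uri, role, label, superclass = NULL) {
  structure(
    list(uri = uri, role = role, label = label, superclass = superclass),
    class = "vocab_term"
  )
}

#' @export
print.vocab_term <- function(x, ...) {
  cat(sprintf("<vocab_term %s> %s '%s'%s\n", x$role, x$uri, x$label,
    if (!is.null(x$superclass)) paste0(" subClassOf ", x$superclass) else ""
  ))
  invisible(x)
}

#' RDF class for an SBML element kind
#'
#' Maps an element kind (or `"model"` for the model resource itself) to
#' its class term in the `sbmlrdf` vocabulary. Every element class is a
#' subclass of `SBMLElement`, itself a subclass of the format-neutral
#' `Element`; the model class `SBMLModel` sits directly under `Element`.
#' `ListOfX` containers have no class: they are dissolved during
#' conversion and asking for one is an error.
#'
#' @param kind one of `"model"`, `"compartment"`, `"species"`, `"reaction"`,
#'   `"species_reference"`, `"parameter"`, `"unit_definition"`, `"rule"`.
#' @return A `vocab_term` with role `"class"`.
#' @examples
#' class_for("species")$uri
#' @export
class_for <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 || is.na(match(kind, names(.CLASS_LOCAL)))) {
    stop("no RDF class for element kind '", paste(kind, collapse = ","), "'", call. = FALSE)
  }
  local <- .CLASS_LOCAL[[kind]]
  superclass <- if (kind == "model") sbmlrdf_uri("Element") else sbmlrdf_uri("SBMLElement")
  new_vocab_term(sbmlrdf_uri(local), "class", local, superclass)
}

#' RDF property for an SBML attribute or structural relation
#'
#' Attribute-derived properties keep the SBML attribute name as their
#' local name (e.g. `initialAmount` maps to `sbmlrdf:initialAmount`);
#' structural relations cover model membership (`species`, `reaction`,
#' ...), reaction participation (`reactant`, `product`, `modifier`) and
#' the `species` link from a species reference to its species.
#'
#' @param name attribute or relation name.
#' @return A `vocab_term` with role `"property"`.
#' @examples
#' property_for("species")$uri
#' property_for("notes")$uri
#' @export
property_for <- function(name) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name) ||
      !(name %in% .KNOWN_PROPERTIES)) {
    stop("no RDF property for '", paste(name, collapse = ","), "'", call. = FALSE)
  }
  new_vocab_term(sbmlrdf_uri(name), "property", name)
}

member_property <- function(kind) property_for(.MEMBER_PROP[[kind]])

#' URI of a BioModels qualifier
#'
#' Builds the URI of a biology (`bqbiol`) or model (`bqmodel`) qualifier
#' from its local name, e.g. `is`, `isVersionOf`, `isDescribedBy`.
#'
#' @param tag `"bqbiol"` or `"bqmodel"`.
#' @param local qualifier local name, non-empty.
#' @param namespaces a namespace table, see [ns_table()].
#' @return Absolute qualifier URI.
#' @examples
#' qualifier_uri("bqbiol", "is")
#' @export
qualifier_uri <- function(tag, local, namespaces = ns_table()) {
  if (!tag %in% c("bqbiol", "bqmodel")) {
    stop("unknown qualifier namespace tag '", tag, "'", call. = FALSE)
  }
  if (!is.character(local) || length(local) != 1 || !nzchar(local)) {
    stop("qualifier local name must be a non-empty string", call. = FALSE)
  }
  paste0(namespaces[[tag]], local)
}

#' The vocabulary schema graph
#'
#' The class hierarchy of the conversion vocabulary as an RDF graph:
#' one `rdfs:subClassOf` triple per class (every element class under
#' `SBMLElement` under `Element`) and an `rdfs:label` for each term.
#' The schema is emitted separately from converted model graphs so that
#' per-model triple counts stay attributable to model content.
#'
#' @return An [rdf_graph].
#' @examples
#' g <- schema_graph()
#' subset(as.data.frame(g), grepl("Species", subject))
#' @export
schema_graph <- function() {
  triples <- list()
  add <- function(t) triples[[length(triples) + 1L]] <<- t

  add(triple_uri(sbmlrdf_uri("SBMLElement"), paste0(.NS_RDFS, "subClassOf"),
    sbmlrdf_uri("Element")))
  add(triple_literal(sbmlrdf_uri("Element"), paste0(.NS_RDFS, "label"), "Element"))
  add(triple_literal(sbmlrdf_uri("SBMLElement"), paste0(.NS_RDFS, "label"), "SBMLElement"))
  for (kind in names(.CLASS_LOCAL)) {
    term <- class_for(kind)
    add(triple_uri(term$uri, paste0(.NS_RDFS, "subClassOf"), term$superclass))
    add(triple_literal(term$uri, paste0(.NS_RDFS, "label"), term$label))
  }
  for (p in sort(unique(.KNOWN_PROPERTIES))) {
    add(triple_literal(sbmlrdf_uri(p), paste0(.NS_RDFS, "label"), p))
  }
  rdf_graph(triples)
}

#' Export the vocabulary schema as Turtle
#'
#' @param path file to write; created or overwritten.
#' @return `path`, invisibly.
#' @export
write_schema_turtle <- function(path) {
  writeLines(serialize_graph(schema_graph(), "turtle"), path, useBytes = TRUE)
  invisible(path)
}
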
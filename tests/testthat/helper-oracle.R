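# Brute-force rule-enumeration oracle for the SBML-to-RDF mapping.
# Walks a parsed model and emits the expected statements as sorted
# N-Triples lines, with its own URI construction, metaid minting,
# literal escaping and math rendering -- sharing no code with the
# converter or vocabulary modules beyond the parsed model object.

ORC_SBMLRDF <- "http://identifiers.org/biomodels.vocabulary#"
ORC_BIODB <- "http://identifiers.org/biomodels.db/"
ORC_RDF_TYPE <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#type"
ORC_OWL_SAMEAS <- "http://www.w3.org/2002/07/owl#sameAs"
ORC_XSD_DOUBLE <- "http://www.w3.org/2001/XMLSchema#double"
ORC_XSD_BOOLEAN <- "http://www.w3.org/2001/XMLSchema#boolean"

ORC_CLASSES <- c(
  compartment = "Compartment", species = "Species", reaction = "Reaction",
  parameter = "Parameter", unit_definition = "UnitDefinition", rule = "Rule"
)
ORC_MEMBER <- c(
  compartment = "compartment", species = "species", reaction = "reaction",
  parameter = "parameter", unit_definition = "unitDefinition", rule = "rule"
)
ORC_DECIMALS <- c("initialAmount", "initialConcentration", "size", "stoichiometry")
ORC_BOOLEANS <- c("reversible", "constant", "boundaryCondition")

orc_escape <- function(x) {
  for (pair in list(c("\\", "\\\\"), c("\"", "\\\""), c("\n", "\\n"),
    c("\r", "\\r"), c("\t", "\\t"))) {
    x <- gsub(pair[1], pair[2], x, fixed = TRUE)
  }
  x
}

orc_line_uri <- function(s, p, o) paste0("<", s, "> <", p, "> <", o, "> .")
orc_line_lit <- function(s, p, v, dt = NULL) {
  paste0("<", s, "> <", p, "> \"", orc_escape(v), "\"",
    if (!is.null(dt)) paste0("^^<", dt, ">") else "", " .")
}

# independent metaid minting: existing id, else meta_<sbml_id>, else
# meta_gen<counter>; species references skolemized off the reaction
orc_assign_metaids <- function(model) {
  used <- character()
  note <- function(e) if (!is.null(e$metaid)) used <<- c(used, e$metaid)
  note(model)
  for (el in c(model$compartments, model$species, model$reactions,
      model$parameters, model$unit_definitions, model$rules)) {
    note(el)
    for (r in c(el$children$reactants, el$children$products, el$children$modifiers)) {
      note(r)
    }
  }
  counter <- 0L
  mint <- function(el) {
    if (!is.null(el$metaid)) return(el)
    if (!is.null(el$sbml_id)) {
      cand <- paste0("meta_", el$sbml_id)
    } else {
      counter <<- counter + 1L
      cand <- sprintf("meta_gen%04d", counter)
    }
    m <- cand
    k <- 1L
    while (m %in% used) {
      k <- k + 1L
      m <- paste0(cand, k)
    }
    used <<- c(used, m)
    el$metaid <- m
    el
  }
  for (f in c("compartments", "species")) model[[f]] <- lapply(model[[f]], mint)
  model$reactions <- lapply(model$reactions, function(rx) {
    rx <- mint(rx)
    for (role in c("reactants", "products", "modifiers")) {
      refs <- rx$children[[role]]
      if (!length(refs)) next
      rx$children[[role]] <- lapply(seq_along(refs), function(i) {
        ref <- refs[[i]]
        if (is.null(ref$metaid)) {
          cand <- paste0(rx$metaid, ".", sub("s$", "", role), ".", i)
          m <- cand
          k <- 1L
          while (m %in% used) {
            k <- k + 1L
            m <- paste0(cand, ".", k)
          }
          used <<- c(used, m)
          ref$metaid <- m
        }
        ref
      })
    }
    rx
  })
  for (f in c("parameters", "unit_definitions", "rules")) {
    model[[f]] <- lapply(model[[f]], mint)
  }
  model
}

# minimal independent MathML walker (covers the operators the fixture
# generator emits)
orc_math <- function(xml_string) {
  node <- xml2::xml_root(xml2::read_xml(xml_string))
  walk <- function(n) {
    nm <- xml2::xml_name(n)
    kids <- as.list(xml2::xml_children(n))
    if (nm == "math") return(walk(kids[[1]]))
    if (nm %in% c("ci", "cn", "csymbol")) return(trimws(xml2::xml_text(n)))
    if (nm == "apply") {
      op <- xml2::xml_name(kids[[1]])
      args <- vapply(kids[-1], walk, character(1))
      sym <- c(plus = "+", minus = "-", times = "*", divide = "/")[op]
      if (!is.na(sym)) {
        if (op == "minus" && length(args) == 1) return(paste0("(-", args, ")"))
        return(paste0("(", paste(args, collapse = paste0(" ", sym, " ")), ")"))
      }
      if (op == "power") return(paste0("(", args[1], "^", args[2], ")"))
      return(paste0(op, "(", paste(args, collapse = ", "), ")"))
    }
    stop("oracle cannot render <", nm, ">")
  }
  walk(node)
}

ORC_SAMEAS <- list(
  uniprot = function(id) paste0("http://purl.uniprot.org/uniprot/", id),
  chebi = function(id) paste0("http://purl.obolibrary.org/obo/", gsub(":", "_", id)),
  go = function(id) paste0("http://purl.obolibrary.org/obo/", gsub(":", "_", id)),
  taxonomy = function(id) paste0("http://purl.obolibrary.org/obo/NCBITaxon_", id),
  reactome = function(id) {
    paste0("http://www.reactome.org/cgi-bin/eventbrowser_st_id?ST_ID=", id)
  }
)

orc_sameas <- function(uri) {
  m <- regmatches(uri, regexec("^http://identifiers\\.org/([^/]+)/(.+)$", uri))[[1]]
  if (length(m) != 3) return(character())
  fn <- ORC_SAMEAS[[m[2]]]
  if (is.null(fn)) character() else fn(m[3])
}

orc_qualifier_uri <- function(ns, local) {
  base <- c(bqbiol = "http://biomodels.net/biology-qualifiers/",
    bqmodel = "http://biomodels.net/model-qualifiers/")[ns]
  if (is.na(base)) paste0(ns, local) else paste0(base, local)
}

# expected sorted N-Triples lines for one converted model
oracle_ntriples <- function(model, curated) {
  model <- orc_assign_metaids(model)
  muri <- paste0(ORC_BIODB, model$model_id)
  euri <- function(metaid) paste0(muri, "#", metaid)
  species_meta <- list()
  for (sp in model$species) species_meta[[sp$sbml_id]] <- sp$metaid
  comp_meta <- list()
  for (cp in model$compartments) {
    if (!is.null(cp$sbml_id)) comp_meta[[cp$sbml_id]] <- cp$metaid
  }

  lines <- character()
  put <- function(l) lines[[length(lines) + 1L]] <<- l
  put_ann <- function(uri, ann) {
    if (!nrow(ann)) return()
    for (i in seq_len(nrow(ann))) {
      put(orc_line_uri(uri, orc_qualifier_uri(ann$ns[i], ann$local[i]), ann$uri[i]))
    }
  }

  put(orc_line_uri(muri, ORC_RDF_TYPE, paste0(ORC_SBMLRDF, "SBMLModel")))
  if (!is.null(model$name)) put(orc_line_lit(muri, paste0(ORC_SBMLRDF, "name"), model$name))
  put(orc_line_lit(muri, paste0(ORC_SBMLRDF, "curated"),
    if (curated) "true" else "false", ORC_XSD_BOOLEAN))
  if (!is.null(model$notes_text)) {
    put(orc_line_lit(muri, paste0(ORC_SBMLRDF, "notes"), model$notes_text))
  }
  put_ann(muri, model$annotations)

  emit <- function(el, uri, class_local) {
    put(orc_line_uri(uri, ORC_RDF_TYPE, paste0(ORC_SBMLRDF, class_local)))
    if (!is.null(el$sbml_id)) put(orc_line_lit(uri, paste0(ORC_SBMLRDF, "id"), el$sbml_id))
    if (!is.null(el$name)) put(orc_line_lit(uri, paste0(ORC_SBMLRDF, "name"), el$name))
    if (!is.null(el$notes_text)) {
      put(orc_line_lit(uri, paste0(ORC_SBMLRDF, "notes"), el$notes_text))
    }
    for (nm in names(el$attributes_raw)) {
      raw <- el$attributes_raw[[nm]]
      pred <- paste0(ORC_SBMLRDF, nm)
      if (nm == "compartment" && raw %in% names(comp_meta)) {
        put(orc_line_uri(uri, pred, euri(comp_meta[[raw]])))
      } else if (nm %in% ORC_DECIMALS && !is.na(suppressWarnings(as.numeric(raw)))) {
        put(orc_line_lit(uri, pred, raw, ORC_XSD_DOUBLE))
      } else if (nm %in% ORC_BOOLEANS && raw %in% c("true", "false", "1", "0")) {
        put(orc_line_lit(uri, pred,
          if (raw %in% c("true", "1")) "true" else "false", ORC_XSD_BOOLEAN))
      } else {
        put(orc_line_lit(uri, pred, raw))
      }
    }
    put_ann(uri, el$annotations)
  }

  kinds <- list(
    compartment = model$compartments, species = model$species,
    reaction = model$reactions, parameter = model$parameters,
    unit_definition = model$unit_definitions, rule = model$rules
  )
  for (kind in names(kinds)) {
    for (el in kinds[[kind]]) {
      uri <- euri(el$metaid)
      put(orc_line_uri(muri, paste0(ORC_SBMLRDF, ORC_MEMBER[[kind]]), uri))
      emit(el, uri, ORC_CLASSES[[kind]])
      if (kind == "reaction") {
        for (role in c("reactants", "products", "modifiers")) {
          for (ref in el$children[[role]]) {
            ruri <- euri(ref$metaid)
            put(orc_line_uri(uri, paste0(ORC_SBMLRDF, sub("s$", "", role)), ruri))
            emit(ref, ruri, "SpeciesReference")
            put(orc_line_uri(ruri, paste0(ORC_SBMLRDF, "species"),
              euri(species_meta[[ref$species]])))
          }
        }
      }
      if (kind %in% c("reaction", "rule") && !is.null(el$math)) {
        put(orc_line_lit(uri, paste0(ORC_SBMLRDF, "notes"), orc_math(el$math)))
      }
    }
  }

  anns <- model$annotations$uri
  for (el in c(model$compartments, model$species, model$reactions,
      model$parameters, model$unit_definitions, model$rules)) {
    anns <- c(anns, el$annotations$uri)
  }
  for (res in unique(anns)) {
    for (canon in orc_sameas(res)) put(orc_line_uri(res, ORC_OWL_SAMEAS, canon))
  }

  sort(unique(lines), method = "radix")
}
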
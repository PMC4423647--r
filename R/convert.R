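# SBML model -> RDF graph conversion. One pass assigns a stable metaid
# to every element (so every resource is a dereferenceable URI, never a
# blank node); a second pass enumerates the triples: typed element
# resources under the vocabulary classes, attribute properties with
# typed literals, flattened qualifier annotations, owl:sameAs bridges,
# and membership links from the model resource to each top-level
# element. ListOf containers and rdf:Bag scaffolding never reach the
# output.

#' Fill in metaids across a parsed model
#'
#' Returns a copy of the model in which every element (including the
#' reactant/product/modifier species references of each reaction)
#' carries a metaid: existing metaids verbatim, minted ones via
#' [ensure_metaid()]; species references without metaids are skolemized
#' as `<reactionMetaid>.<role>.<ordinal>` so their URIs stay stable and
#' sortable.
#'
#' @param model an [sbml_model].
#' @return The model with all metaids populated.
#' @export
assign_metaids <- function(model) {
  state <- metaid_state(model)
  fill <- function(el) {
    el$metaid <- ensure_metaid(el, model, state)
    el
  }
  for (field in c("compartments", "species")) {
    model[[field]] <- lapply(model[[field]], fill)
  }
  model$reactions <- lapply(model$reactions, function(rx) {
    rx <- fill(rx)
    for (role in c("reactants", "products", "modifiers")) {
      refs <- rx$children[[role]]
      if (!length(refs)) next
      singular <- sub("s$", "", role)
      rx$children[[role]] <- lapply(seq_along(refs), function(i) {
        ref <- refs[[i]]
        if (is.null(ref$metaid)) {
          candidate <- paste0(rx$metaid, ".", singular, ".", i)
          k <- 1L
          metaid <- candidate
          while (metaid %in% state$used) {
            k <- k + 1L
            metaid <- paste0(candidate, ".", k)
          }
          state$used <- c(state$used, metaid)
          ref$metaid <- metaid
        }
        ref
      })
    }
    rx
  })
  for (field in c("parameters", "unit_definitions", "rules")) {
    model[[field]] <- lapply(model[[field]], fill)
  }
  model
}

#' Convert a parsed SBML model to an RDF graph
#'
#' Applies the full mapping: the model resource is typed
#' `sbmlrdf:SBMLModel` and carries its name, notes and the `curated`
#' flag (recording whether the model passed manual curation); each
#' element becomes a typed resource linked from the model by a
#' kind-specific membership property, with one property triple per
#' source attribute (decimal/boolean literals where the attribute is
#' numeric/logical, the `compartment` attribute resolved to the
#' compartment's URI), one direct qualifier triple per flattened
#' annotation link, and `owl:sameAs` statements for cross-references
#' with known canonical URIs. Reactions link to their skolemized
#' `SpeciesReference` resources, which point at the participating
#' species via `sbmlrdf:species`. Kinetic-law and rule math is attached
#' as an infix string under `sbmlrdf:notes`.
#'
#' @param model an [sbml_model] from [parse_sbml()].
#' @param curated logical: is this a curated-branch model?
#' @param policy a [uri_policy()].
#' @return An [rdf_graph] named by the model URI.
#' @examples
#' g <- convert_model(parse_sbml(paper_fragment()), curated = TRUE)
#' n_triples(g)
#' @export
convert_model <- function(model, curated = FALSE, policy = uri_policy()) {
  stopifnot(inherits(model, "sbml_model"), is.logical(curated), length(curated) == 1)
  existing <- collect_metaids(model)
  if (anyDuplicated(existing)) {
    stop("duplicate metaid(s) in source document: ",
      paste(unique(existing[duplicated(existing)]), collapse = ", "),
      call. = FALSE)
  }
  model <- assign_metaids(model)
  mid <- model$model_id
  muri <- model_uri(mid, policy)
  rdf_type <- paste0(.NS_RDF, "type")
  owl_sameas <- paste0(.NS_OWL, "sameAs")

  species_meta <- named_metaids(model$species)
  compartment_meta <- named_metaids(model$compartments)

  triples <- list()
  add <- function(t) triples[[length(triples) + 1L]] <<- t

  add(triple_uri(muri, rdf_type, class_for("model")$uri))
  if (!is.null(model$name)) {
    add(triple_literal(muri, sbmlrdf_uri("name"), model$name))
  }
  add(triple_literal(muri, sbmlrdf_uri("curated"),
    if (curated) "true" else "false", XSD_BOOLEAN))
  if (!is.null(model$notes_text)) {
    add(triple_literal(muri, sbmlrdf_uri("notes"), model$notes_text))
  }
  for (t in annotation_triples(muri, model$annotations)) add(t)

  emit_element <- function(el, uri) {
    add(triple_uri(uri, rdf_type, class_for(el$kind)$uri))
    if (!is.null(el$sbml_id)) add(triple_literal(uri, sbmlrdf_uri("id"), el$sbml_id))
    if (!is.null(el$name)) add(triple_literal(uri, sbmlrdf_uri("name"), el$name))
    if (!is.null(el$notes_text)) {
      add(triple_literal(uri, sbmlrdf_uri("notes"), el$notes_text))
    }
    for (nm in names(el$attributes)) {
      v <- el$attributes[[nm]]
      raw <- el$attributes_raw[[nm]]
      pred <- sbmlrdf_uri(nm)
      if (nm == "compartment" && is.character(v) && v %in% names(compartment_meta)) {
        add(triple_uri(uri, pred, element_uri(mid, compartment_meta[[v]], policy)))
      } else if (is.numeric(v)) {
        add(triple_literal(uri, pred, raw, XSD_DOUBLE))
      } else if (is.logical(v)) {
        add(triple_literal(uri, pred, if (v) "true" else "false", XSD_BOOLEAN))
      } else {
        add(triple_literal(uri, pred, raw))
      }
    }
    for (t in annotation_triples(uri, el$annotations)) add(t)
  }

  for (kind_field in list(
    c("compartment", "compartments"), c("species", "species"),
    c("reaction", "reactions"), c("parameter", "parameters"),
    c("unit_definition", "unit_definitions"), c("rule", "rules")
  )) {
    kind <- kind_field[1]
    for (el in model[[kind_field[2]]]) {
      uri <- element_uri(mid, el$metaid, policy)
      add(triple_uri(muri, member_property(kind)$uri, uri))
      emit_element(el, uri)

      if (kind == "reaction") {
        for (role in c("reactants", "products", "modifiers")) {
          rel <- property_for(sub("s$", "", role))$uri
          for (ref in el$children[[role]]) {
            if (!ref$species %in% names(species_meta)) {
              stop("reaction '", el$sbml_id %||% el$metaid,
                "' references unknown species '", ref$species, "'", call. = FALSE)
            }
            ref_uri <- element_uri(mid, ref$metaid, policy)
            add(triple_uri(uri, rel, ref_uri))
            emit_element(ref, ref_uri)
            add(triple_uri(ref_uri, sbmlrdf_uri("species"),
              element_uri(mid, species_meta[[ref$species]], policy)))
          }
        }
      }
      if (kind %in% c("reaction", "rule")) {
        mt <- convert_math(el, mid, policy)
        if (!is.null(mt)) add(mt)
      }
    }
  }

  # owl:sameAs bridges for every distinct cross-referenced resource
  all_ann <- rbind(model$annotations,
    do.call(rbind, c(list(annotation_links()),
      lapply(all_elements(model), function(e) e$annotations))))
  for (res in unique(all_ann$uri)) {
    for (canonical in same_as_uris(res, policy)) {
      add(triple_uri(res, owl_sameas, canonical))
    }
  }

  rdf_graph(triples, name = muri)
}

named_metaids <- function(elements) {
  ids <- vapply(elements, function(e) e$sbml_id %||% NA_character_, character(1))
  metas <- vapply(elements, function(e) e$metaid, character(1))
  stats::setNames(metas, ids)[!is.na(ids)]
}

annotation_triples <- function(uri, links) {
  if (!nrow(links)) return(list())
  out <- list()
  for (i in seq_len(nrow(links))) {
    tag <- links$ns[i]
    pred <- if (tag %in% c("bqbiol", "bqmodel")) {
      qualifier_uri(tag, links$local[i])
    } else if (is_absolute_uri(tag)) {
      paste0(tag, links$local[i])
    } else {
      log_note("dropping annotation with unusable qualifier namespace '",
        tag, "' on ", uri)
      next
    }
    out[[length(out) + 1L]] <- triple_uri(uri, pred, links$uri[i])
  }
  out
}

#' Math-as-string triple for a reaction or rule
#'
#' The RDF form deliberately does not model MathML semantics; equations
#' travel as infix strings on `sbmlrdf:notes`. Returns `NULL` when the
#' element has no math.
#'
#' @param reaction_or_rule an [sbml_element] of kind reaction or rule,
#'   with its metaid assigned.
#' @param model_id the containing model's id.
#' @param policy a [uri_policy()].
#' @return A one-row triple data.frame, or `NULL`.
#' @export
convert_math <- function(reaction_or_rule, model_id, policy = uri_policy()) {
  el <- reaction_or_rule
  if (is.null(el$math)) return(NULL)
  triple_literal(
    element_uri(model_id, el$metaid, policy),
    sbmlrdf_uri("notes"),
    mathml_to_infix(el$math)
  )
}

#' Parse and convert an SBML file in one step
#'
#' @param path SBML file.
#' @param curated logical curation flag.
#' @param policy a [uri_policy()].
#' @return An [rdf_graph].
#' @export
convert_file <- function(path, curated = FALSE, policy = uri_policy()) {
  convert_model(parse_sbml(path), curated = curated, policy = policy)
}
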
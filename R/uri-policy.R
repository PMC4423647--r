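# Identifiers.org URI minting for models and their elements, plus the
# owl:sameAs bridge from Identifiers.org cross-references to canonical
# provider URIs.

#' URI minting policy
#'
#' Controls how model and element URIs are built and which canonical
#' equivalents are asserted for Identifiers.org cross-references. The
#' defaults reproduce the BioModels scheme: model URIs under
#' `http://identifiers.org/biomodels.db/` and element URIs formed by a
#' hash fragment holding the element's SBML metaid.
#'
#' @param model_namespace URI prefix for model resources; must end in
#'   `/`.
#' @param fragment_separator separator between model URI and element
#'   metaid (default `"#"`).
#' @param sameas_table data.frame with columns `collection` and
#'   `template` mapping an Identifiers.org collection prefix to a
#'   canonical URI template. Templates contain `{id}` (record
#'   identifier verbatim) or `{id_}` (identifier with `:` replaced by
#'   `_`, for OBO PURLs). `NULL` disables sameAs generation;
#'   [default_sameas_table()] ships entries for uniprot, chebi, go,
#'   taxonomy and reactome.
#' @return An object of class `uri_policy`.
#' @examples
#' policy <- uri_policy()
#' model_uri("BIOMD0000000001", policy)
#' @export
uri_policy <- function(model_namespace = "http://identifiers.org/biomodels.db/",
                       fragment_separator = "#",
                       sameas_table = default_sameas_table()) {
  if (!is.character(model_namespace) || !endsWith(model_namespace, "/")) {
    stop("model_namespace must be a URI prefix ending in '/'", call. = FALSE)
  }
  if (is.null(sameas_table)) {
    sameas_table <- data.frame(collection = character(), template = character(),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(sameas_table),
    all(c("collection", "template") %in% names(sameas_table)))
  structure(
    list(model_namespace = model_namespace,
      fragment_separator = fragment_separator,
      sameas_table = sameas_table),
    class = "uri_policy"
  )
}

#' Default canonical-URI table for owl:sameAs statements
#'
#' Read from the package's `sameas_default.tsv`; covers the collections
#' most used to annotate curated models (UniProt, ChEBI, GO, NCBI
#' taxonomy, Reactome). Use [read_sameas_table()] to load a custom
#' table.
#'
#' @return data.frame with columns `collection`, `template`.
#' @export
default_sameas_table <- function() {
  read_sameas_table(system.file("extdata", "sameas_default.tsv",
    package = "sbml2rdf", mustWork = TRUE))
}

#' Load a sameAs configuration table
#'
#' @param path TSV file with header columns `collection` and
#'   `template`.
#' @return data.frame with columns `collection`, `template`.
#' @export
read_sameas_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("collection", "template") %in% names(tab))) {
    stop("sameAs table needs 'collection' and 'template' columns: ", path,
      call. = FALSE)
  }
  tab
}

#' Model URI
#'
#' @param model_id BioModels-style identifier, non-empty, no
#'   whitespace.
#' @param policy a [uri_policy()].
#' @return `model_namespace` + `model_id`.
#' @examples
#' model_uri("BIOMD0000000008")
#' @export
model_uri <- function(model_id, policy = uri_policy()) {
  if (!is.character(model_id) || length(model_id) != 1 || !nzchar(model_id) ||
      grepl("[[:space:]]", model_id)) {
    stop("model_id must be a non-empty string without whitespace", call. = FALSE)
  }
  paste0(policy$model_namespace, model_id)
}

#' Element URI
#'
#' Element resources are identified by the model URI plus a hash
#' fragment carrying the element's SBML metaid, verbatim (leading
#' underscores are not escaped).
#'
#' @param model_id model identifier.
#' @param metaid the element's metaid, non-empty.
#' @param policy a [uri_policy()].
#' @return Absolute element URI.
#' @examples
#' element_uri("BIOMD0000000008", "202866")
#' @export
element_uri <- function(model_id, metaid, policy = uri_policy()) {
  if (!is.character(metaid) || length(metaid) != 1 || !nzchar(metaid)) {
    stop("metaid must be non-empty; mint one with ensure_metaid() first",
      call. = FALSE)
  }
  paste0(model_uri(model_id, policy), policy$fragment_separator, metaid)
}

#' Fresh metaid-minting state
#'
#' @param model optionally, an [sbml_model]: its existing metaids seed
#'   the used set so minted ids cannot collide with them.
#' @return An environment holding the used-metaid set and the counter
#'   for anonymous elements.
#' @export
metaid_state <- function(model = NULL) {
  state <- new.env(parent = emptyenv())
  state$used <- character()
  state$counter <- 0L
  if (!is.null(model)) state$used <- collect_metaids(model)
  state
}

collect_metaids <- function(model) {
  out <- character()
  grab <- function(e) if (!is.null(e$metaid)) out[[length(out) + 1L]] <<- e$metaid
  if (!is.null(model$metaid)) out <- c(out, model$metaid)
  for (el in all_elements(model)) {
    grab(el)
    for (ref in c(el$children$reactants, el$children$products, el$children$modifiers)) {
      grab(ref)
    }
  }
  out
}

all_elements <- function(model) {
  c(model$compartments, model$species, model$reactions, model$parameters,
    model$unit_definitions, model$rules)
}

#' Return or deterministically mint an element's metaid
#'
#' Annotation-bearing elements in non-curated models do not always
#' carry metaids; a URI fragment is minted for them, stable across
#' runs: the element's own metaid if present, else `meta_` + its SBML
#' id, else `meta_gen` + zero-padded counter in document order.
#' Collisions with existing metaids get a numeric suffix.
#'
#' @param element an [sbml_element].
#' @param model the containing [sbml_model] (unused when the element
#'   already has a metaid; kept for the calling convention).
#' @param state a [metaid_state()]; mutated to record the returned id.
#' @return The metaid string, unique within `state`.
#' @export
ensure_metaid <- function(element, model = NULL, state = metaid_state(model)) {
  if (!is.null(element$metaid) && nzchar(element$metaid)) {
    state$used <- union(state$used, element$metaid)
    return(element$metaid)
  }
  if (!is.null(element$sbml_id) && nzchar(element$sbml_id)) {
    candidate <- paste0("meta_", element$sbml_id)
  } else {
    state$counter <- state$counter + 1L
    candidate <- sprintf("meta_gen%04d", state$counter)
  }
  metaid <- candidate
  k <- 1L
  while (metaid %in% state$used) {
    k <- k + 1L
    metaid <- paste0(candidate, k)
  }
  state$used <- c(state$used, metaid)
  metaid
}

#' Canonical equivalents of an Identifiers.org cross-reference
#'
#' Applies the policy's sameAs templates to an Identifiers.org URI of
#' the form `http://identifiers.org/<collection>/<id>`. Unknown
#' collections and non-Identifiers.org URIs yield an empty result;
#' these are not errors, canonical URIs simply exist only for some
#' providers.
#'
#' @param resource_uri absolute URI.
#' @param policy a [uri_policy()].
#' @return Character vector of canonical URIs (possibly empty).
#' @examples
#' same_as_uris("http://identifiers.org/uniprot/P12345")
#' @export
same_as_uris <- function(resource_uri, policy = uri_policy()) {
  stopifnot(is_absolute_uri(resource_uri))
  m <- regmatches(resource_uri,
    regexec("^http://identifiers\\.org/([^/]+)/(.+)$", resource_uri))[[1]]
  if (length(m) != 3) return(character())
  templates <- policy$sameas_table$template[policy$sameas_table$collection == m[2]]
  if (!length(templates)) return(character())
  id <- m[3]
  out <- gsub("{id_}", gsub(":", "_", id, fixed = TRUE), templates, fixed = TRUE)
  gsub("{id}", id, out, fixed = TRUE)
}
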
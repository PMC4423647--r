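# Embedded triple store and SPARQL query layer. The store itself is an
# in-memory set of triples with byte-stable N-Triples export; SPARQL 1.1
# evaluation (including SERVICE passthrough for federated queries) is
# delegated to the Python rdflib engine available on the PATH, via the
# helper script shipped in inst/python/. Canned model-exploration
# queries are thin conveniences that substitute their parameters into
# the documented query templates in inst/queries/ and run them through
# the same generic engine.

#' Create an empty triple store
#'
#' @return An object of class `rdf_store` holding zero triples.
#' @seealso [store_load()] to add graphs or serialized files.
#' @export
rdf_store <- function() {
  structure(list(triples = empty_triples()), class = "rdf_store")
}

#' @export
print.rdf_store <- function(x, ...) {
  cat(sprintf("<rdf_store: %d triples>\n", nrow(x$triples)))
  invisible(x)
}

#' Load graphs or RDF files into a store
#'
#' Accepts [rdf_graph] objects, paths to N-Triples (`.nt`) or Turtle
#' (`.ttl`) files, or lists mixing both. The store has set semantics:
#' loading the same statements twice leaves the count unchanged.
#' Turtle files are parsed through the rdflib engine; N-Triples
#' natively.
#'
#' @param store an [rdf_store()].
#' @param x graph, file path, or list/vector of either.
#' @return The updated store.
#' @export
store_load <- function(store, x) {
  stopifnot(inherits(store, "rdf_store"))
  items <- if (inherits(x, "rdf_graph")) list(x)
  else if (is.character(x)) as.list(x)
  else if (is.list(x)) x
  else stop("cannot load object of class ", paste(class(x), collapse = "/"),
    call. = FALSE)

  parts <- list(store$triples)
  for (item in items) {
    if (inherits(item, "rdf_graph")) {
      parts[[length(parts) + 1L]] <- item$triples
    } else if (is.character(item) && length(item) == 1) {
      parts[[length(parts) + 1L]] <- read_rdf_file(item)$triples
    } else {
      stop("cannot load item of class ", paste(class(item), collapse = "/"),
        call. = FALSE)
    }
  }
  store$triples <- rdf_graph(do.call(rbind, parts))$triples
  store
}

#' Read an RDF file into a graph
#'
#' @param path `.nt`/`.ntriples` (parsed natively) or `.ttl`/`.turtle`
#'   (parsed via the rdflib engine) file.
#' @return An [rdf_graph].
#' @export
read_rdf_file <- function(path) {
  if (!file.exists(path)) stop("RDF file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nt", "ntriples")) {
    g <- tryCatch(
      parse_ntriples(readLines(path, warn = FALSE, encoding = "UTF-8")),
      error = function(e) stop("cannot parse ", path, ": ",
        conditionMessage(e), call. = FALSE)
    )
    return(g)
  }
  if (!ext %in% c("ttl", "turtle")) {
    stop("unsupported RDF file extension '", ext, "' for ", path, call. = FALSE)
  }
  out <- run_python_helper(c("to_nt", "--data", path))
  if (out$status != 0L) {
    stop("cannot parse ", path, ": ", out$stderr, call. = FALSE)
  }
  parse_ntriples(out$stdout)
}

store_nt_lines <- function(store) sort_c(ntriples_lines(store$triples))

#' Write a store or graph as sorted N-Triples
#'
#' @param x an [rdf_store] or [rdf_graph].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(x, path) {
  lines <- if (inherits(x, "rdf_store")) store_nt_lines(x)
  else sort_c(ntriples_lines(x$triples))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

find_python <- function() {
  cached <- getOption("sbml2rdf.python")
  if (!is.null(cached)) return(cached)
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) {
      options(sbml2rdf.python = unname(p))
      return(unname(p))
    }
  }
  stop("no python interpreter found on PATH (needed for SPARQL evaluation)",
    call. = FALSE)
}

helper_script <- function() {
  system.file("python", "sparql_query.py", package = "sbml2rdf", mustWork = TRUE)
}

run_python_helper <- function(args) {
  err_file <- tempfile("sparql-err-")
  on.exit(unlink(err_file), add = TRUE)
  stdout <- suppressWarnings(system2(find_python(), c(shQuote(helper_script()),
    args), stdout = TRUE, stderr = err_file))
  status <- attr(stdout, "status") %||% 0L
  stderr_txt <- if (file.exists(err_file)) {
    paste(readLines(err_file, warn = FALSE), collapse = "\n")
  } else ""
  list(status = status, stdout = paste(stdout, collapse = "\n"),
    stderr = stderr_txt)
}

#' Run a SPARQL query over a store
#'
#' Standard SPARQL 1.1 evaluation (SELECT or ASK). `SERVICE` clauses
#' are passed through to the engine for federated execution against
#' remote endpoints; a remote failure is reported distinctly from a
#' local one.
#'
#' @param store an [rdf_store].
#' @param query_text SPARQL query string, or path to a `.rq` file.
#' @return A `query_result`: a data.frame with one column per selected
#'   variable (term strings; unbound bindings are `NA`), with the
#'   variable list in attribute `"vars"`. ASK queries return a logical
#'   scalar.
#' @examples
#' \dontrun{
#' store <- store_load(rdf_store(), convert_model(parse_sbml(paper_fragment())))
#' run_sparql(store, "SELECT ?s WHERE { ?s ?p ?o } LIMIT 2")
#' }
#' @export
run_sparql <- function(store, query_text) {
  stopifnot(inherits(store, "rdf_store"))
  if (length(query_text) == 1 && !grepl("\n", query_text) &&
      grepl("\\.rq$", query_text) && file.exists(query_text)) {
    query_text <- paste(readLines(query_text, warn = FALSE, encoding = "UTF-8"),
      collapse = "\n")
  }
  data_file <- tempfile("store-", fileext = ".nt")
  query_file <- tempfile("query-", fileext = ".rq")
  on.exit(unlink(c(data_file, query_file)), add = TRUE)
  writeLines(store_nt_lines(store), data_file, useBytes = TRUE)
  writeLines(query_text, query_file, useBytes = TRUE)

  out <- run_python_helper(c("query", "--data", data_file, "--query", query_file))
  if (out$status == 2L) {
    stop("SPARQL syntax error: ", out$stderr, call. = FALSE)
  }
  if (out$status == 4L) {
    stop("federated query failed at the remote endpoint: ", out$stderr,
      call. = FALSE)
  }
  if (out$status != 0L) {
    stop("SPARQL evaluation failed: ", out$stderr, call. = FALSE)
  }
  parse_sparql_json(out$stdout)
}

parse_sparql_json <- function(txt) {
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.null(parsed$boolean)) return(isTRUE(parsed$boolean))
  vars <- vapply(parsed$head$vars, identity, character(1))
  bindings <- parsed$results$bindings
  cols <- lapply(vars, function(v) {
    vapply(bindings, function(row) {
      if (is.null(row[[v]])) NA_character_ else row[[v]]$value
    }, character(1))
  })
  names(cols) <- vars
  res <- as.data.frame(cols, stringsAsFactors = FALSE, optional = TRUE)
  if (!length(bindings)) {
    res <- as.data.frame(stats::setNames(
      replicate(length(vars), character(), simplify = FALSE), vars),
      stringsAsFactors = FALSE)
  }
  attr(res, "vars") <- vars
  class(res) <- c("query_result", "data.frame")
  res
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("<query_result: %d rows of (%s)>\n", nrow(x),
    paste(attr(x, "vars"), collapse = ", ")))
  if (nrow(x)) print.data.frame(utils::head(x, 20))
  invisible(x)
}

query_template <- function(name, substitutions = list()) {
  path <- system.file("queries", paste0(name, ".rq"), package = "sbml2rdf",
    mustWork = TRUE)
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  for (key in names(substitutions)) {
    text <- gsub(paste0("%", key, "%"), substitutions[[key]], text, fixed = TRUE)
  }
  text
}

#' List the species of a model
#'
#' One row per species resource of the model, with its name bound where
#' the species is named.
#'
#' @param store an [rdf_store].
#' @param model_id model identifier (e.g. `"BIOMD0000000001"`).
#' @param policy a [uri_policy()] used to mint the model URI.
#' @return A `query_result` with variables `species`, `name`.
#' @export
species_in_model <- function(store, model_id, policy = uri_policy()) {
  run_sparql(store, query_template("species_in_model",
    list(MODEL_URI = model_uri(model_id, policy))))
}

#' Find elements annotated with a concept
#'
#' Every element carrying any bqbiol/bqmodel qualifier triple whose
#' object is the given concept URI, with the qualifier used and the
#' model the element belongs to.
#'
#' @param store an [rdf_store].
#' @param concept_uri absolute concept URI (e.g. a GO term's
#'   Identifiers.org URI).
#' @return A `query_result` with variables `element`, `qualifier`,
#'   `model`.
#' @export
elements_by_annotation <- function(store, concept_uri) {
  stopifnot(is_absolute_uri(concept_uri))
  run_sparql(store, query_template("elements_by_annotation",
    list(CONCEPT_URI = concept_uri)))
}

#' Find elements annotated into a collection, by URI prefix
#'
#' Pattern-matching over annotation URIs: returns every qualifier
#' triple whose object starts with the given prefix (for instance the
#' Identifiers.org Reactome collection), with the element's type.
#'
#' @param store an [rdf_store].
#' @param collection_prefix URI prefix string.
#' @return A `query_result` with variables `element`, `type`,
#'   `qualifier`, `annotation`.
#' @export
elements_by_collection <- function(store, collection_prefix) {
  stopifnot(is.character(collection_prefix), length(collection_prefix) == 1,
    nzchar(collection_prefix))
  run_sparql(store, query_template("elements_by_collection",
    list(COLLECTION_PREFIX = collection_prefix)))
}

#' Models annotated with all of several concepts
#'
#' Conjunctive search: a model qualifies when, for every concept in the
#' collection, the model or one of its elements is annotated with that
#' concept. With `reactions = TRUE` the result also lists each
#' qualifying model's reactions (the form used to find, for example,
#' reactions involving calcium ions in the cytosol of rat).
#'
#' @param store an [rdf_store].
#' @param concept_uris non-empty character vector of concept URIs.
#' @param reactions logical: also bind each model's reactions?
#' @return A `query_result` with variable `model` (plus `reaction`).
#' @export
models_with_all_concepts <- function(store, concept_uris, reactions = FALSE) {
  if (!length(concept_uris)) {
    stop("concept_uris must contain at least one concept URI", call. = FALSE)
  }
  run_sparql(store, build_all_concepts_query(concept_uris, reactions))
}

#' SPARQL text of the conjunctive concept query
#'
#' @inheritParams models_with_all_concepts
#' @return Query string.
#' @export
build_all_concepts_query <- function(concept_uris, reactions = FALSE) {
  stopifnot(all(vapply(concept_uris, is_absolute_uri, logical(1))))
  blocks <- vapply(seq_along(concept_uris), function(i) {
    c_uri <- concept_uris[[i]]
    paste0(
      "  {\n",
      "    ?model ?q", i, " <", c_uri, "> .\n",
      "    FILTER(STRSTARTS(STR(?q", i, "), \"http://biomodels.net/\"))\n",
      "  } UNION {\n",
      "    ?model ?m", i, " ?e", i, " .\n",
      "    ?e", i, " ?q", i, " <", c_uri, "> .\n",
      "    FILTER(STRSTARTS(STR(?m", i,
      "), \"http://identifiers.org/biomodels.vocabulary#\"))\n",
      "    FILTER(STRSTARTS(STR(?q", i, "), \"http://biomodels.net/\"))\n",
      "  }"
    )
  }, character(1))
  paste0(
    "PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>\n",
    "PREFIX sbmlrdf: <http://identifiers.org/biomodels.vocabulary#>\n",
    "SELECT DISTINCT ?model", if (reactions) " ?reaction" else "", "\nWHERE {\n",
    "  ?model rdf:type sbmlrdf:SBMLModel .\n",
    if (reactions) "  ?model sbmlrdf:reaction ?reaction .\n" else "",
    paste(blocks, collapse = "\n"),
    "\n}\n"
  )
}
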
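# Dataset statistics over a converted corpus: the counted summary the
# BioModels linked dataset publishes with each release (models, typed
# species and reactions, cross-references, distinct concepts, and the
# distinct species/reactions deduced from their annotation sets).

.BQBIOL_NS <- paste0(.NS_BQBIOL_BASE, "/")
.QUALIFIER_ROOT <- "http://biomodels.net/"

#' Read a curation manifest
#'
#' Tab-separated `model_id<TAB>curated` lines (a `model_id`/`curated`
#' header row is allowed); the curated column accepts
#' true/false, 1/0, yes/no.
#'
#' @param path TSV file.
#' @return data.frame with columns `model_id` (character) and `curated`
#'   (logical).
#' @export
read_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^model_id\\b", lines[1])) lines <- lines[-1]
  if (!length(lines)) {
    return(data.frame(model_id = character(), curated = logical(),
      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 2
  if (any(bad)) {
    stop("manifest line without a tab-separated curated flag: ",
      lines[which(bad)[1]], call. = FALSE)
  }
  data.frame(
    model_id = vapply(parts, `[`, character(1), 1),
    curated = tolower(vapply(parts, `[`, character(1), 2)) %in%
      c("true", "1", "yes"),
    stringsAsFactors = FALSE
  )
}

#' Corpus statistics of a converted store
#'
#' Counts, over all loaded model graphs (the schema graph is emitted
#' separately and should not be loaded): total triples; resources typed
#' `Species` and `Reaction`; cross-reference (qualifier) triples whose
#' object is an Identifiers.org URI and the distinct concepts they
#' point to; and the distinct annotated species/reactions. Two
#' elements count as the same "distinct" species (or reaction) when
#' their biology-qualifier annotation signatures -- the set of bqbiol
#' resource URIs -- coincide; elements without annotations are not
#' counted. `distinct_by = "concept"` switches to the coarser
#' alternative of counting distinct annotation URIs in use on that
#' element class. Model counts come from the curation manifest.
#'
#' @param store an [rdf_store].
#' @param curation_manifest data.frame with `model_id` and `curated`
#'   columns (see [read_manifest()]), or a path to a manifest TSV;
#'   `NULL` for zero model counts.
#' @param distinct_by `"signature"` (default) or `"concept"`.
#' @param policy [uri_policy()] used to check that manifest models are
#'   present in the store.
#' @return A `dataset_stats` object (named list of counts).
#' @export
compute_stats <- function(store, curation_manifest = NULL,
                          distinct_by = c("signature", "concept"),
                          policy = uri_policy()) {
  stopifnot(inherits(store, "rdf_store"))
  distinct_by <- match.arg(distinct_by)
  tr <- store$triples
  rdf_type <- paste0(.NS_RDF, "type")

  if (is.character(curation_manifest)) {
    curation_manifest <- read_manifest(curation_manifest)
  }
  n_curated <- n_noncurated <- 0L
  if (!is.null(curation_manifest) && nrow(curation_manifest)) {
    n_curated <- sum(curation_manifest$curated)
    n_noncurated <- sum(!curation_manifest$curated)
    model_uris <- vapply(curation_manifest$model_id, model_uri, character(1),
      policy = policy)
    typed_models <- tr$object == class_for("model")$uri & tr$predicate == rdf_type
    missing <- !model_uris %in% tr$subject[typed_models]
    if (any(missing)) {
      warning("manifest model(s) not found in store: ",
        paste(curation_manifest$model_id[missing], collapse = ", "),
        call. = FALSE)
    }
  }

  is_qualifier <- startsWith(tr$predicate, .QUALIFIER_ROOT)
  is_crossref <- is_qualifier & tr$object_kind == "uri" &
    startsWith(tr$object, .NS_IDORG)

  typed_subjects <- function(kind) {
    unique(tr$subject[tr$predicate == rdf_type & tr$object == class_for(kind)$uri])
  }
  species <- typed_subjects("species")
  reactions <- typed_subjects("reaction")

  distinct_annotated <- function(subjects) {
    is_bqbiol <- startsWith(tr$predicate, .BQBIOL_NS) & tr$subject %in% subjects
    if (!any(is_bqbiol)) return(0L)
    if (distinct_by == "concept") {
      return(length(unique(tr$object[is_bqbiol])))
    }
    sig <- vapply(
      split(tr$object[is_bqbiol], tr$subject[is_bqbiol]),
      function(uris) paste(sort_c(unique(uris)), collapse = "\n"),
      character(1)
    )
    length(unique(sig))
  }

  structure(list(
    n_models_curated = as.integer(n_curated),
    n_models_noncurated = as.integer(n_noncurated),
    n_triples = nrow(tr),
    n_species = length(species),
    n_distinct_annotated_species = distinct_annotated(species),
    n_reactions = length(reactions),
    n_distinct_reactions_by_annotation = distinct_annotated(reactions),
    n_crossref_triples = sum(is_crossref),
    n_distinct_concepts = length(unique(tr$object[is_crossref]))
  ), class = "dataset_stats")
}

#' @export
print.dataset_stats <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%-36s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Histogram of annotations by collection or qualifier
#'
#' Groups cross-reference triples by Identifiers.org collection (the
#' path segment after `identifiers.org/`; only Identifiers.org objects
#' participate, so the counts sum to `n_crossref_triples`) or groups
#' all qualifier triples by their qualifier predicate.
#'
#' @param store an [rdf_store].
#' @param by `"collection"` or `"qualifier"`.
#' @return data.frame with columns `key` and `count`, sorted by key.
#' @export
annotation_histogram <- function(store, by = c("collection", "qualifier")) {
  stopifnot(inherits(store, "rdf_store"))
  if (!is.character(by) || !by[1] %in% c("collection", "qualifier")) {
    stop("unknown grouping key '", by[1], "'", call. = FALSE)
  }
  by <- by[1]
  tr <- store$triples
  is_qualifier <- startsWith(tr$predicate, .QUALIFIER_ROOT)
  if (by == "collection") {
    keep <- is_qualifier & tr$object_kind == "uri" &
      startsWith(tr$object, .NS_IDORG)
    keys <- sub("^http://identifiers\\.org/([^/]+)/.*$", "\\1", tr$object[keep])
  } else {
    keys <- tr$predicate[is_qualifier]
  }
  if (!length(keys)) {
    return(data.frame(key = character(), count = integer(),
      stringsAsFactors = FALSE))
  }
  counts <- table(keys)
  data.frame(key = sort_c(names(counts)),
    count = as.integer(counts[sort_c(names(counts))]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write dataset statistics as JSON
#'
#' @param stats a `dataset_stats` from [compute_stats()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE)
  invisible(path)
}
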
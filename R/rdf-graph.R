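# RDF triples are held in a plain data.frame with one row per statement:
#   subject, predicate          absolute URIs
#   object                      URI or literal lexical form
#   object_kind                 "uri" or "literal"
#   datatype                    datatype URI for typed literals, NA for
#                               plain string literals and URI objects
# Set semantics are enforced on construction by deduplicating canonical
# N-Triples lines.

XSD_DOUBLE <- "http://www.w3.org/2001/XMLSchema#double"
XSD_BOOLEAN <- "http://www.w3.org/2001/XMLSchema#boolean"

#' Build a triple with a URI object
#'
#' @param subject,predicate,object absolute URIs.
#' @return One-row triple data.frame.
#' @export
triple_uri <- function(subject, predicate, object) {
  stopifnot(is_absolute_uri(subject), is_absolute_uri(predicate), is_absolute_uri(object))
  data.frame(
    subject = subject, predicate = predicate, object = object,
    object_kind = "uri", datatype = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Build a triple with a literal object
#'
#' @param subject,predicate absolute URIs.
#' @param value literal lexical form (character scalar).
#' @param datatype datatype URI, or `NA` for a plain string literal.
#' @return One-row triple data.frame.
#' @export
triple_literal <- function(subject, predicate, value, datatype = NA_character_) {
  stopifnot(is_absolute_uri(subject), is_absolute_uri(predicate),
    is.character(value), length(value) == 1, !is.na(value))
  data.frame(
    subject = subject, predicate = predicate, object = value,
    object_kind = "literal", datatype = datatype,
    stringsAsFactors = FALSE
  )
}

is_absolute_uri <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) && grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)
}

empty_triples <- function() {
  data.frame(
    subject = character(), predicate = character(), object = character(),
    object_kind = character(), datatype = character(),
    stringsAsFactors = FALSE
  )
}

#' An RDF graph
#'
#' A set of subject-predicate-object statements with an optional graph
#' name (used as the named-graph URI when a multi-model dataset is
#' emitted). Duplicate statements are collapsed: a graph has set
#' semantics.
#'
#' @param triples a data.frame of triples (rows from [triple_uri()] /
#'   [triple_literal()]), or a list of such data.frames.
#' @param name optional graph-name URI.
#' @return An object of class `rdf_graph`.
#' @examples
#' g <- rdf_graph(triple_uri("http://example.org/s", "http://example.org/p",
#'   "http://example.org/o"))
#' n_triples(g)
#' @export
rdf_graph <- function(triples = empty_triples(), name = NULL) {
  if (is.list(triples) && !is.data.frame(triples)) {
    triples <- if (length(triples)) do.call(rbind, triples) else empty_triples()
  }
  stopifnot(is.data.frame(triples))
  lines <- ntriples_lines(triples)
  keep <- !duplicated(lines)
  triples <- triples[keep, , drop = FALSE]
  rownames(triples) <- NULL
  structure(list(triples = triples, name = name), class = "rdf_graph")
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph%s: %d triples>\n",
    if (!is.null(x$name)) paste0(" ", x$name) else "", nrow(x$triples)))
  invisible(x)
}

#' @export
as.data.frame.rdf_graph <- function(x, ...) x$triples

#' Number of statements in a graph or store
#'
#' @param x an `rdf_graph` or `rdf_store`.
#' @return Integer count of distinct triples.
#' @export
n_triples <- function(x) {
  if (inherits(x, "rdf_graph")) nrow(x$triples)
  else if (inherits(x, "rdf_store")) nrow(x$triples)
  else stop("n_triples() expects an rdf_graph or rdf_store", call. = FALSE)
}

escape_ntriples <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_ntriples <- function(x) {
  # process escape pairs left to right so "\\n" stays a literal backslash-n
  vapply(x, function(s) {
    out <- character()
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t", "\\" = "\\", "\"" = "\"",
          paste0("\\", nxt)
        ))
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

format_object <- function(object, object_kind, datatype) {
  ifelse(
    object_kind == "uri",
    paste0("<", object, ">"),
    paste0(
      "\"", escape_ntriples(object), "\"",
      ifelse(is.na(datatype), "", paste0("^^<", datatype, ">"))
    )
  )
}

ntriples_lines <- function(triples) {
  if (!nrow(triples)) return(character())
  paste0(
    "<", triples$subject, "> <", triples$predicate, "> ",
    format_object(triples$object, triples$object_kind, triples$datatype), " ."
  )
}

sort_c <- function(x) sort(x, method = "radix")

#' Serialize a graph to Turtle or N-Triples
#'
#' N-Triples output is sorted lexicographically (byte order), so two
#' structurally identical graphs always serialize to identical bytes.
#' Turtle output carries the standard prefix block and is likewise
#' sorted.
#'
#' @param graph an [rdf_graph].
#' @param format `"turtle"` or `"ntriples"`.
#' @param namespaces prefix table used for Turtle compaction.
#' @return A single character scalar (UTF-8); empty string for an empty
#'   N-Triples graph.
#' @export
serialize_graph <- function(graph, format = c("turtle", "ntriples"),
                            namespaces = ns_table()) {
  stopifnot(inherits(graph, "rdf_graph"))
  if (!is.character(format) || length(format) < 1 ||
      !format[1] %in% c("turtle", "ntriples")) {
    stop("unknown serialization format '", paste(format[1]), "'", call. = FALSE)
  }
  format <- format[1]
  lines <- sort_c(ntriples_lines(graph$triples))
  if (format == "ntriples") {
    return(if (length(lines)) paste0(paste(lines, collapse = "\n"), "\n") else "")
  }
  prefixes <- sprintf("@prefix %s: <%s> .", names(namespaces), unname(namespaces))
  body <- vapply(lines, turtle_compact_line, character(1),
    namespaces = namespaces, USE.NAMES = FALSE)
  paste0(paste(c(prefixes, "", body), collapse = "\n"), "\n")
}

# Compact the URIs of one sorted N-Triples line into prefixed names where
# the local part is safe; literals are left untouched.
turtle_compact_line <- function(line, namespaces) {
  m <- regmatches(line, regexec("^<([^>]*)> <([^>]*)> (.*) \\.$", line))[[1]]
  s <- turtle_term(m[2], namespaces)
  p <- turtle_term(m[3], namespaces)
  o <- m[4]
  if (startsWith(o, "<")) {
    o <- turtle_term(substr(o, 2, nchar(o) - 1L), namespaces)
  } else {
    dt <- regmatches(o, regexec("\\^\\^<([^>]*)>$", o))[[1]]
    if (length(dt) == 2) {
      o <- sub("\\^\\^<[^>]*>$", paste0("^^", turtle_term(dt[2], namespaces)), o)
    }
  }
  paste0(s, " ", p, " ", o, " .")
}

turtle_term <- function(uri, namespaces) {
  for (i in seq_along(namespaces)) {
    ns <- namespaces[[i]]
    if (startsWith(uri, ns)) {
      local <- substring(uri, nchar(ns) + 1L)
      if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)) {
        return(paste0(names(namespaces)[i], ":", local))
      }
    }
  }
  paste0("<", uri, ">")
}

#' Parse N-Triples text into a graph
#'
#' Line-oriented parser for the N-Triples subset this package emits
#' (URI subjects/predicates, URI or literal objects with optional
#' datatype). Blank-node terms are rejected: converted graphs are fully
#' skolemized.
#'
#' @param x character vector of lines, or a single string with newlines.
#' @param name optional graph name.
#' @return An [rdf_graph].
#' @export
parse_ntriples <- function(x, name = NULL) {
  if (length(x) == 1 && grepl("\n", x)) x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  x <- x[nzchar(trimws(x))]
  x <- x[!startsWith(trimws(x), "#")]
  if (!length(x)) return(rdf_graph(name = name))
  m <- regmatches(x, regexec(
    "^\\s*<([^>]*)>\\s+<([^>]*)>\\s+(.*?)\\s*\\.\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop("not valid N-Triples at line ", which(bad)[1], ": ", x[which(bad)[1]],
      call. = FALSE)
  }
  subj <- vapply(m, `[`, character(1), 2)
  pred <- vapply(m, `[`, character(1), 3)
  obj_raw <- vapply(m, `[`, character(1), 4)
  parsed <- lapply(obj_raw, parse_nt_object)
  rdf_graph(data.frame(
    subject = subj, predicate = pred,
    object = vapply(parsed, `[[`, character(1), "object"),
    object_kind = vapply(parsed, `[[`, character(1), "object_kind"),
    datatype = vapply(parsed, `[[`, character(1), "datatype"),
    stringsAsFactors = FALSE
  ), name = name)
}

parse_nt_object <- function(o) {
  if (startsWith(o, "<") && endsWith(o, ">")) {
    return(list(object = substr(o, 2, nchar(o) - 1L),
      object_kind = "uri", datatype = NA_character_))
  }
  if (startsWith(o, "_:")) {
    stop("blank nodes are not supported: ", o, call. = FALSE)
  }
  m <- regmatches(o, regexec('^"(.*)"(?:\\^\\^<([^>]*)>|@([A-Za-z-]+))?$', o))[[1]]
  if (!length(m)) stop("cannot parse N-Triples object: ", o, call. = FALSE)
  list(
    object = unescape_ntriples(m[2]),
    object_kind = "literal",
    datatype = if (nzchar(m[3])) m[3] else NA_character_
  )
}

#' Merge graphs into one
#'
#' @param ... `rdf_graph` objects or lists of them.
#' @param name optional name for the merged graph.
#' @return An [rdf_graph] containing the distinct union of all input
#'   statements.
#' @export
merge_graphs <- function(..., name = NULL) {
  gs <- list(...)
  flat <- list()
  for (g in gs) {
    if (inherits(g, "rdf_graph")) flat[[length(flat) + 1L]] <- g
    else flat <- c(flat, g)
  }
  rdf_graph(lapply(flat, function(g) g$triples), name = name)
}
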
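# Small hand-rolled SBML documents for targeted cases.

SBML_L3_OPEN <- paste0(
  "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
  "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\"",
  " level=\"3\" version=\"1\">"
)

wrap_sbml <- function(model_body, model_id = "TESTMODEL", metaid = NULL,
                      name = NULL) {
  paste0(
    SBML_L3_OPEN,
    "<model id=\"", model_id, "\"",
    if (!is.null(metaid)) paste0(" metaid=\"", metaid, "\"") else "",
    if (!is.null(name)) paste0(" name=\"", name, "\"") else "",
    ">", model_body, "</model></sbml>"
  )
}

bag_annotation <- function(about, entries) {
  # entries: list of list(ns = "bqbiol", local = "is", uris = c(...))
  quals <- vapply(entries, function(e) {
    paste0(
      "<", e$ns, ":", e$local, "><rdf:Bag>",
      paste0("<rdf:li rdf:resource=\"", e$uris, "\"/>", collapse = ""),
      "</rdf:Bag></", e$ns, ":", e$local, ">"
    )
  }, character(1))
  paste0(
    "<annotation><rdf:RDF",
    " xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
    " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\"",
    " xmlns:bqmodel=\"http://biomodels.net/model-qualifiers/\">",
    "<rdf:Description rdf:about=\"#", about, "\">",
    paste(quals, collapse = ""),
    "</rdf:Description></rdf:RDF></annotation>"
  )
}

sorted_nt <- function(graph) {
  lines <- strsplit(serialize_graph(graph, "ntriples"), "\n", fixed = TRUE)[[1]]
  sort(lines[nzchar(lines)], method = "radix")
}

# store built from one or more models' converted graphs
fixture_store <- function(...) {
  store_load(rdf_store(), list(...))
}

all_elements_of <- function(model) {
  c(model$compartments, model$species, model$reactions, model$parameters,
    model$unit_definitions, model$rules)
}
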
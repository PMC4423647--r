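Package: sbml2rdf
Title: Convert Systems Biology Markup Language Models to Linked RDF
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic conversion of SBML (Systems Biology Markup
    Language, Level 2/3 core) models into RDF under a BioModels-style
    vocabulary. Elements (compartments, species, reactions, parameters,
    unit definitions, rules) become typed resources identified by
    Identifiers.org URIs with metaid fragments; ListOf containers are
    dissolved; controlled-vocabulary annotations (bqbiol/bqmodel
    qualifiers) are flattened from their rdf:Bag form into direct
    element-to-resource triples, with optional owl:sameAs bridges to
    canonical provider URIs. Includes byte-stable Turtle and N-Triples
    writers, an embedded SPARQL query layer with the canonical
    model-exploration queries, dataset statistics (species, reactions,
    cross-references, distinct annotated concepts), a reproducible
    synthetic-model generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the rdflib package on the PATH
    (used for SPARQL evaluation).
Config/testthat/edition: 3
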
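# sbml2rdf

Deterministic conversion of SBML models (Level 2/3 core) into linked
RDF, with an embedded SPARQL query layer and dataset statistics.

Kinetic models of biological processes are exchanged as SBML: XML
listing compartments, species, reactions, parameters, unit definitions
and rules, with each element annotated by controlled-vocabulary
cross-references (`bqbiol`/`bqmodel` qualifiers pointing at
Identifiers.org URIs for GO terms, ChEBI entities, UniProt proteins,
taxa, pathways). `sbml2rdf` is for people who want to *query across*
such models — modellers looking for comparable models, curators
auditing annotation coverage, data integrators joining model content
with other linked datasets — without scripting over every XML file.

## The mapping in brief

Each model becomes a graph of subject–predicate–object triples:

* model resource `http://identifiers.org/biomodels.db/<id>`, typed
  `sbmlrdf:SBMLModel`, with `sbmlrdf:name`, `sbmlrdf:notes` and a
  boolean `sbmlrdf:curated` flag;
* one resource per element at `<modelURI>#<metaid>`, typed
  `sbmlrdf:Species`, `sbmlrdf:Reaction`, ... (all subclasses of
  `sbmlrdf:SBMLElement` ⊂ `sbmlrdf:Element`), linked from the model by
  a membership property per kind — the XML `ListOfX` containers are
  dissolved;
* attributes as same-named properties with typed literals
  (`xsd:double` for amounts/sizes/stoichiometry, `xsd:boolean` for
  flags), the `compartment` attribute resolved to the compartment's
  URI;
* annotations flattened out of their `rdf:Bag` form into direct
  `(element, qualifier, resource)` triples, plus `owl:sameAs` bridges
  to canonical provider URIs where known;
* reaction participants as skolemized `sbmlrdf:SpeciesReference`
  resources pointing at their species via `sbmlrdf:species`;
* kinetic-law and rule math rendered to infix strings under
  `sbmlrdf:notes` (MathML semantics are deliberately not modelled).

Missing metaids are minted deterministically, no blank nodes are ever
emitted, and N-Triples output is byte-order sorted — identical input
gives byte-identical files. See the vignette
(`vignettes/sbml-to-rdf-methods.Rmd`) for the full rules and design
rationale.

## Worked example

```r
library(sbml2rdf)

model <- parse_sbml(paper_fragment())   # or a path to any SBML file
model
#> <sbml_model BIOMD0000000001 (L2V4) 'Edelstein1996 - EPSP ACh event'>
#>   compartments: 1  species: 2  reactions: 1
#>   parameters: 1  unit definitions: 0  rules: 0  annotations: 2

graph <- convert_model(model, curated = TRUE)
graph
#> <rdf_graph http://identifiers.org/biomodels.db/BIOMD0000000001: 43 triples>

store <- store_load(rdf_store(), graph)
species_in_model(store, "BIOMD0000000001")
#> <query_result: 2 rows of (species, name)>
#>                                                       species      name
#> 1 http://identifiers.org/biomodels.db/BIOMD0000000001#_000003  BasalACh
#> 2 http://identifiers.org/biomodels.db/BIOMD0000000001#_000004 BasalACh2

compute_stats(store, data.frame(model_id = "BIOMD0000000001", curated = TRUE))
#> n_models_curated                     1
#> n_models_noncurated                  0
#> n_triples                            43
#> n_species                            2
#> n_distinct_annotated_species         2
#> n_reactions                          1
#> n_distinct_reactions_by_annotation   0
#> n_crossref_triples                   5
#> n_distinct_concepts                  4
```

The species URIs are the model URI plus the element's SBML metaid as
fragment; the two species each carry GO channel-complex annotations,
hence two distinct annotation signatures; the reaction is unannotated,
so it contributes nothing to the distinct-reaction count; 5 of the 43
triples are cross-references, reaching 4 distinct concepts.

Ad-hoc SPARQL works over the same store, e.g. counting species:

```r
run_sparql(store, system.file("queries", "count_species.rq", package = "sbml2rdf"))
#> <query_result: 1 rows of (count)>
#>   count
#> 1     2
```

A shell front end wraps the same functions
(`system.file("cli", "sbml2rdf", package = "sbml2rdf")`):

```sh
sbml2rdf convert model.xml model.ttl --curated
sbml2rdf batch models/ rdf/ --manifest manifest.tsv --format ntriples
sbml2rdf stats rdf/*.nt --manifest manifest.tsv --json stats.json
sbml2rdf query rdf/*.nt --query inst/queries/species_in_model.rq
```

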
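---
title: "Mapping SBML models to linked RDF: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping SBML models to linked RDF: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbml2rdf)
```

## The problem

Repositories of kinetic models in systems biology store their content as
SBML: XML documents whose model element groups compartments, species,
reactions, parameters, unit definitions and rules into `ListOfX`
containers, and whose elements carry controlled-vocabulary annotations —
`rdf:Bag`s of Identifiers.org resource URIs under BioModels biology
(`bqbiol`) and model (`bqmodel`) qualifiers. That representation is
excellent for exchange and simulation but awkward for cross-model,
cross-resource search: answering "which models contain reactions
involving calcium ions in the cytosol of rat?" requires downloading
every model and scripting over the XML.

`sbml2rdf` converts each model into an RDF graph under a small
vocabulary so that such questions become SPARQL queries over a triple
store. The conversion is deliberately *lossy in one direction only*:
structure and annotations are preserved as first-class triples, while
mathematics is carried along as strings. The RDF form complements the
SBML file; it does not replace it.

## The mapping

One model document produces one named graph. The rules are:

* **The model resource** is `http://identifiers.org/biomodels.db/<id>`,
  typed `sbmlrdf:SBMLModel`, carrying `sbmlrdf:name`, `sbmlrdf:notes`
  (flattened XHTML) and a boolean `sbmlrdf:curated` recording whether
  the model passed manual curation. The curated flag is supplied from
  outside the document (per-call flag or a curation manifest): SBML
  itself does not record it.
* **Elements** become resources at `<modelURI>#<metaid>`, typed with
  the class for their kind (`sbmlrdf:Species`, `sbmlrdf:Reaction`, ...).
  Every element class is a subclass of `sbmlrdf:SBMLElement`, itself a
  subclass of the format-neutral `sbmlrdf:Element` (the hook under
  which other model formats could be attached). The model class sits
  directly under `Element` since it is not an SBML element itself. The
  hierarchy is emitted as a separate schema graph
  (`schema_graph()`) so per-model triple counts remain attributable to
  model content.
* **`ListOfX` containers are dissolved.** Their children link directly
  from the model resource through one membership property per kind
  (`sbmlrdf:species`, `sbmlrdf:reaction`, ...). No resource of any
  "ListOf" type ever appears in the output.
* **Attributes** map to properties with the same local name
  (`sbmlrdf:initialAmount`, `sbmlrdf:reversible`, ...).
  `initialAmount`, `initialConcentration`, `size` and `stoichiometry`
  are typed `xsd:double`; `reversible`, `constant` and
  `boundaryCondition` are `xsd:boolean`; everything else is a plain
  string. The `compartment` attribute is resolved to the compartment
  element's URI — the species-to-compartment arrow is a class-to-class
  relation, not a name — falling back to a string literal when the
  referenced compartment does not exist in the document. The SBML `id`
  attribute is kept as `sbmlrdf:id` (it is how modellers refer to
  elements), while `metaid` is not re-emitted: it already forms the URI
  fragment.
* **Annotations are flattened.** Each `rdf:li` resource inside a
  qualifier's `rdf:Bag` yields one direct triple
  `(element, qualifierURI, resourceURI)`; the bag scaffolding is
  discarded. Qualifiers from unrecognized namespaces are retained with
  their namespace recorded verbatim and a log note, so nothing is
  silently dropped. For cross-references whose provider publishes a
  canonical URI (UniProt, ChEBI, GO, NCBI taxonomy, Reactome by
  default; configurable via a TSV table) an `owl:sameAs` bridge is
  added.
* **Reaction participants** are `sbmlrdf:SpeciesReference` resources
  linked from the reaction via `sbmlrdf:reactant` / `sbmlrdf:product` /
  `sbmlrdf:modifier` and pointing at the participating species via
  `sbmlrdf:species`, with stoichiometry as a decimal literal when
  present.
* **Math is a string.** Kinetic laws and rule equations render to an
  infix formula attached under `sbmlrdf:notes`; MathML semantics are
  otherwise omitted. Unrenderable MathML falls back to its raw text,
  logged.

```{r example}
model <- parse_sbml(paper_fragment())
graph <- convert_model(model, curated = TRUE)
cat(substr(serialize_graph(graph, "turtle"), 1, 400))
```

## URIs, metaids and skolemization

Element URIs are *metaid fragments*: `<modelURI>#<metaid>`, metaid
verbatim. Annotation-bearing elements in non-curated models do not
always carry metaids, so missing ones are minted deterministically:
`meta_` + the SBML id when present, else `meta_gen` + a zero-padded
document-order counter, with a numeric suffix on collision. Species
references without metaids are skolemized as
`<reactionMetaid>.<role>.<ordinal>`. Blank nodes are never emitted:
they would break dereferencing and make sorted serialization
non-deterministic. The same reasoning drives the serializers:
N-Triples output is sorted in byte order, so structurally identical
graphs are byte-identical files.

Two separator choices are configurable because the published namespace
table prints bare namespaces: vocabulary terms use `#` after
`http://identifiers.org/biomodels.vocabulary`, and qualifier URIs use
`/` after the BioModels.net qualifier namespaces (the form the
qualifier registry has historically used). The exact local names of the
relation properties (`reactant`, `product`, `modifier`) and of the
model class `SBMLModel` are this package's own choices, mirroring SBML
role names; the published vocabulary prints only `sbmlrdf:species` and
`sbmlrdf:notes` among them.

## The query layer

Converted graphs load into an embedded store with set semantics.
SPARQL 1.1 evaluation is delegated to the `rdflib` engine of the Python
interpreter on the PATH through a bundled helper script; the store
ships its triples to the engine as canonical N-Triples per query. This
keeps correctness — a mature, standards-complete SPARQL implementation —
while the store, converter and statistics remain native R. `SERVICE`
clauses pass through untouched, so federated queries against remote
endpoints are expressible; the shipped federated examples
(`inst/queries/federated_*.rq`) are documentation only and excluded
from tests, since remote endpoints move.

The four canned query families — species of a model, elements by
concept, elements by collection prefix, models annotated with all of a
set of concepts — are conveniences that substitute parameters into the
documented `.rq` templates under `inst/queries/` and run them through
the same generic engine. The conjunctive family accepts any number of
concepts, so its text is built programmatically
(`build_all_concepts_query()`) in the same shape for every arity.
The element-to-model binding in the annotation query derives the model
URI from the element URI's fragment, which also covers annotations
sitting on the model resource itself.

## Dataset statistics

`compute_stats()` counts: total triples; resources typed `Species` and
`Reaction`; cross-reference triples (qualifier predicates with
Identifiers.org objects) and the distinct concepts they reach; and
"distinct" annotated species/reactions. Distinctness groups elements by
their *biology-qualifier annotation signature* — the set of `bqbiol`
resource URIs on the element; elements without annotations are not
counted. The coarser alternative (counting distinct annotation URIs in
use) is selectable with `distinct_by = "concept"`; the signature
interpretation is the default because equality of the full annotation
set is what justifies calling two pools of entities "the same species"
across models. Model counts come from the curation manifest, with a
warning for manifest entries absent from the store. The schema graph
is emitted separately and should not be loaded when counting.

## The synthetic-model generator

Testing needs corpora with known ground truth, so the generator builds
SBML Level 3 documents from a seed and records a ledger of exactly what
it drew: per-kind element counts, every annotation link, and the
annotation-signature sets. Its defaults describe a typical curated
literature model — 12 species in 2 compartments, 8 reactions, 2
parameters, one rule and one unit definition, with annotations on 80%
of elements drawn from a pool spanning GO, ChEBI, UniProt, taxonomy and
Reactome — reflecting that curated models are small and densely
annotated. Bags occasionally carry several `rdf:li` entries and a
second qualifier (`bqbiol:isVersionOf`) so flattening is genuinely
exercised; names come from a fixed word list, numbers are formatted
with fixed precision, and identical specs are byte-identical.

What the generator does *not* emulate: SBML package extensions, nested
`rdf:Description` annotation blocks, function definitions and events,
local kinetic-law parameters, and the very large automatically
generated pathway models. Passing tests therefore demonstrate the
mapping's correctness on core-SBML literature-style models, not
performance at repository scale, and corpus-scale statistics from this
package on real releases depend on the documented mapping choices
(notes triples, `sbmlrdf:id`, sameAs table contents, stoichiometry and
species-reference typing).

A separate hand-built fragment mirrors the shape of the repository's
first curated entry (an acetylcholine receptor model): its species
carries metaid `_000003` and its reversible reaction metaid `_000017`,
pinning the element-URI contract to the published forms.

## Numerical and degenerate-input choices

* Decimal literals keep the source document's lexical form (`1e-16`
  stays `1e-16`): the parser stores the raw attribute string next to
  the typed value, so serialization never depends on R's float
  formatting. Note that loading Turtle back *through the rdflib
  engine* may value-normalize doubles (`"0"` becomes `"0.0"`), an
  RDF-value-preserving change; the native N-Triples path is exact.
* Booleans are normalized to `true`/`false` (SBML also allows `1`/`0`).
* Empty annotation elements, models without species, and queries with
  no matches are ordinary empty results, not errors. Malformed XML, a
  non-SBML root, an unsupported SBML level, a species reference to a
  missing species, and duplicate metaids are hard errors.
* Test problem sizes: the randomized converter-versus-oracle sweep uses
  100 models of up to 7 species and 4 reactions; corpus statistics use
  3–12 models at the generator defaults. These sizes already exercise
  every mapping rule, including minted metaids and skolemized species
  references.

## Known limitations

* One model per file; SBML Level 1 and package-extended constructs are
  rejected or skipped (with a warning).
* Unit definitions are captured as elements, but their inner unit list
  is not represented; rule subtype (assignment/rate/algebraic) is
  likewise not distinguished in RDF.
* Species-reference annotations get qualifier triples but no
  `owl:sameAs` bridges (in practice species references are not
  annotated).
* The query layer requires a Python interpreter with `rdflib` on the
  PATH; without one, conversion, serialization and statistics still
  work, but `run_sparql()` and the canned queries do not.
* RDF/XML and JSON-LD output, reverse RDF-to-SBML conversion, and
  hosting an HTTP SPARQL endpoint are out of scope.
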
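# Every model element annotated with one concept, e.g. the GO term for
# the acetylcholine-gated channel complex (GO:0005892), with the
# qualifier used and the model the element belongs to.
PREFIX sbmlrdf: <http://identifiers.org/biomodels.vocabulary#>
SELECT ?element ?qualifier ?model
WHERE {
  ?element ?qualifier <%CONCEPT_URI%> .
  FILTER(STRSTARTS(STR(?qualifier), "http://biomodels.net/"))
  BIND(IF(CONTAINS(STR(?element), "#"),
          IRI(STRBEFORE(STR(?element), "#")),
          ?element) AS ?model)
}
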
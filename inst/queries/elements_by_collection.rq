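# Pattern-matching on annotation URIs: every element cross-referenced
# into one Identifiers.org collection (e.g. all Reactome pathways),
# with the element type, qualifier and the specific annotation.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
SELECT ?element ?type ?qualifier ?annotation
WHERE {
  ?element ?qualifier ?annotation .
  FILTER(isIRI(?annotation))
  FILTER(STRSTARTS(STR(?annotation), "%COLLECTION_PREFIX%"))
  FILTER(STRSTARTS(STR(?qualifier), "http://biomodels.net/"))
  OPTIONAL { ?element rdf:type ?type }
}
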
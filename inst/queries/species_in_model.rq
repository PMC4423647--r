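# All species of one model, with their names where present.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sbmlrdf: <http://identifiers.org/biomodels.vocabulary#>
SELECT ?species ?name
WHERE {
  <%MODEL_URI%> sbmlrdf:species ?species .
  ?species rdf:type sbmlrdf:Species .
  OPTIONAL { ?species sbmlrdf:name ?name }
}
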
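# Total number of species resources in the loaded dataset.
PREFIX rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#>
PREFIX sbmlrdf: <http://identifiers.org/biomodels.vocabulary#>
SELECT (COUNT(?x) AS ?count)
WHERE { ?x rdf:type sbmlrdf:Species }
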
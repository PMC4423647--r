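# Documentation example (requires network access to the remote
# endpoint): ChEMBL protein targets present in one model, joined via
# shared UniProt cross-references. Not part of the test suite; remote
# endpoints move.
PREFIX sbmlrdf: <http://identifiers.org/biomodels.vocabulary#>
PREFIX bqbiol: <http://biomodels.net/biology-qualifiers/>
PREFIX cco: <http://rdf.ebi.ac.uk/terms/chembl#>
SELECT ?element ?uniprot ?target
WHERE {
  <http://identifiers.org/biomodels.db/BIOMD0000000008> sbmlrdf:species ?element .
  ?element bqbiol:is ?uniprot .
  FILTER(STRSTARTS(STR(?uniprot), "http://identifiers.org/uniprot/"))
  SERVICE <https://www.ebi.ac.uk/rdf/services/sparql> {
    ?target cco:targetCmptXref ?uniprot .
  }
}
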
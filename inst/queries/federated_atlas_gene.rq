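# Documentation example (requires network access to the remote
# endpoint): model elements relating to a gene via UniProt
# cross-references shared with an expression atlas. Not part of the
# test suite; remote endpoints move.
PREFIX atlasterms: <http://rdf.ebi.ac.uk/terms/atlas/>
PREFIX bqbiol: <http://biomodels.net/biology-qualifiers/>
SELECT ?element ?uniprot
WHERE {
  SERVICE <https://www.ebi.ac.uk/rdf/services/sparql> {
    ?expr atlasterms:ref ?uniprot .
  }
  ?element bqbiol:is ?uniprot .
}
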
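# Namespace bases as printed by BioModels (bare, without trailing
# separator), plus the standard RDF namespaces. Loaded first.
.NS_SBMLRDF_BASE <- "http://identifiers.org/biomodels.vocabulary"
.NS_BIODB <- "http://identifiers.org/biomodels.db/"
.NS_BQBIOL_BASE <- "http://biomodels.net/biology-qualifiers"
.NS_BQMODEL_BASE <- "http://biomodels.net/model-qualifiers"

.NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.NS_RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
.NS_OWL <- "http://www.w3.org/2002/07/owl#"
.NS_XSD <- "http://www.w3.org/2001/XMLSchema#"
.NS_IDORG <- "http://identifiers.org/"
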
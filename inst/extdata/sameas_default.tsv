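collection	template
uniprot	http://purl.uniprot.org/uniprot/{id}
chebi	http://purl.obolibrary.org/obo/{id_}
go	http://purl.obolibrary.org/obo/{id_}
taxonomy	http://purl.obolibrary.org/obo/NCBITaxon_{id}
reactome	http://www.reactome.org/cgi-bin/eventbrowser_st_id?ST_ID={id}
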
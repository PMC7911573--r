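record_id	kingdom	phylum	class	order	family	genus	species	its1_should_amplify	its1_fwd_mismatch_positions	its1_plan	its1_insert_len	its2_should_amplify	its2_fwd_mismatch_positions	its2_plan	its2_insert_len
SH010001.97	Fungi	Ascomycota	Eurotiomycetes	Eurotiales	Trichocomaceae	Aspergillus	Aspergillus_fumigatus	TRUE		NA	196	TRUE		NA	273
SH010002.97	Fungi	Ascomycota	Eurotiomycetes	Eurotiales	Trichocomaceae	Aspergillus	Aspergillus_fumigatus	TRUE	12	NA	185	FALSE	11,12,13	consecutive-run	260
SH010003.97	Fungi	Ascomycota	Eurotiomycetes	Eurotiales	Trichocomaceae	Aspergillus	Aspergillus_fumigatus	TRUE	5,8	NA	183	TRUE	14	NA	276
SH010004.97	Fungi	Ascomycota	Eurotiomycetes	Eurotiales	Trichocomaceae	Aspergillus	Aspergillus_fumigatus	TRUE	0,1,15	NA	172	TRUE	12,15	NA	245
SH020001.97	Fungi	Basidiomycota	Agaricomycetes	Cantharellales	Tulasnellaceae	Tulasnella	Tulasnella_calospora	TRUE		NA	186	FALSE	17	3prime-hit	286
SH020002.97	Fungi	Basidiomycota	Agaricomycetes	Cantharellales	Tulasnellaceae	Tulasnella	Tulasnella_calospora	FALSE		missing-site	161	FALSE	17	3prime-hit	268
SH020003.97	Fungi	Basidiomycota	Agaricomycetes	Cantharellales	Tulasnellaceae	Tulasnella	Tulasnella_calospora	FALSE		missing-site	177	FALSE	17	3prime-hit	263
SH020004.97	Fungi	Basidiomycota	Agaricomycetes	Cantharellales	Tulasnellaceae	Tulasnella	Tulasnella_calospora	TRUE	9	NA	183	FALSE	16	3prime-hit	269
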
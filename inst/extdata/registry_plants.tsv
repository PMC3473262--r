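code	name	is_outgroup	is_reference_anchor
At	Arabidopsis thaliana	0	1
Pt	Populus trichocarpa	0	0
Os	Oryza sativa	0	0
Pp	Physcomitrella patens	0	0
Cr	Chlamydomonas reinhardtii	0	0
Syn	Synechocystis sp. PCC6803	1	0
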
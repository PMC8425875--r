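metabolite_id	protein_id	role	source
C00022	LDHA	both	example
C00022	PKM	product	example
C00022	PDHA1	substrate	example
C00031	HK1	substrate	example
C00031	G6PC1	product	example
C00074	PKM	substrate	example
C00074	ENO1	product	example
C00186	LDHA	both	example
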
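species	Coeloplana_loyai	Coeloplana_yulianicorum	Vallicula_multiformis	Mnemiopsis_leidyi	Pleurobrachia_bachei
Coeloplana_loyai	-	0	5	9	11
Coeloplana_yulianicorum	0	-	5	9	11
Vallicula_multiformis	0.38	0.38	-	11	12
Mnemiopsis_leidyi	0.69	0.69	0.85	-	12
Pleurobrachia_bachei	0.85	0.85	0.77	0.92	-
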
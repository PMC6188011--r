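stage	older	younger
Burdigalian	20.44	15.97
Langhian	15.97	13.82
Serravallian	13.82	11.63
Tortonian	11.63	7.246
Messinian	7.246	5.333
Zanclean	5.333	3.6
Piacenzian	3.6	2.58
Gelasian	2.58	1.8
Calabrian	1.8	0.774
Chibanian	0.774	0.129
Upper_Pleistocene	0.129	0.0117
Holocene	0.0117	0.0
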
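gene	neural	mural	endothelial	microglia
Apoe	2	1	3	400
Vegfa	120	8	4	2
Kdr	0	0	150	0
Lrp1	50	12	60	8
Vtn	0	300	2	1
Angpt1	1	90	2	0
Tek	0	1	80	6
Itgb1	30	95	40	25
Actb	500	480	510	490
Xist	3	2	2	3
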
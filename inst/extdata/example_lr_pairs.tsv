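Ligand.ApprovedSymbol	Receptor.ApprovedSymbol
Vegfa	Kdr
Vtn	Kdr
Apoe	Lrp1
Angpt1	Tek
Vtn	Itgb1
Apoe	Ldlr
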
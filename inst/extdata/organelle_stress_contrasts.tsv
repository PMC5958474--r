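geo_id	stress	tissue	comparison
GSE49598	endoplasmic_reticulum	mouse embryonic fibroblast	Perk-/- vs. wild-type
GSE11322	endoplasmic_reticulum	mouse telencephalon	Xbp1-/- vs. wild-type
GSE75150	golgi	mouse embryonic fibroblast	Atf4-/- vs. wild-type
GSE39621	lysosome	mouse brain	Npc1-/- vs. Npc1+/-
GSE56102	lysosome	human embryonal carcinoma NTERA2 D/1 cells	VAMP7 knockdown siRNA vs. control
GSE67227	endosome	mouse liver	Rab5-/- vs. wild-type
GSE40207	mitochondria	mouse testis	ClpP-/- vs. wild-type
GSE60413	mitochondria	mouse cerebellum	Pink1-/- vs. wild-type
GSE67676	autophagy	mouse liver	Atg7 conditional knockout vs. wild-type
GSE13512	autophagy	mouse paneth cells	Atg16l1 mutant vs. wild-type
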
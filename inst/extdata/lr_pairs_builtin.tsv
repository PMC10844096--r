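pair_id	ligand_genes	receptor_genes
IL21_IL21R	IL21	IL21R
TNF_TNFRSF1A	TNF	TNFRSF1A
TGFB1_TGFBR1R2	TGFB1	TGFBR1,TGFBR2
CD40LG_CD40	CD40LG	CD40
CD80_CD28	CD80	CD28
CD86_CD28	CD86	CD28
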
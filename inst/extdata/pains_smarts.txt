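# Compact catalog of well-known pan-assay interference (PAINS-type)
# substructure patterns, one per line: SMARTS <tab> name.
# This is a curated subset of the widely used frequent-hitter motifs
# (quinones, catechols, rhodanine-likes, azo dyes, hydrazones, Mannich
# phenols, beta-keto enols); it is not the full published screen.
O=C1C=CC(=O)C=C1	quinone_para
O=C1C(=O)C=CC=C1	quinone_ortho
[OX2H]c1ccccc1[OX2H]	catechol
[OX2H]c1ccc(O)cc1	hydroquinone
cN=Nc	azo_aromatic
[CX3](=S)[SX2]	thiocarbonyl_sulfide
S=C1SCC(=O)N1	rhodanine
C=C1SC(=S)NC1=O	ene_rhodanine
c[CH]=NN	aryl_hydrazone
C(=O)N[NH2]	acyl_hydrazide
[OX2H][#6X3]=[#6X3][CX3]=O	beta_keto_enol
[NX3][CX3]=[CX3][CX3]=O	enamine_ketone
c1ccc2c(c1)C(=O)c1ccccc1C2=O	anthraquinone
[SX2][SX2]	disulfide
[N+](=O)[O-]	nitro_group
C=[N+]=[N-]	diazo
[CH]=[CH][CH]=[CH][CH]=O	polyene_aldehyde
c1ccc(cc1)C(=O)C=Cc1ccccc1	chalcone
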
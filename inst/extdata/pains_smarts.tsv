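name	smarts
rhodanine	O=C1CSC(=S)N1
ene_rhodanine	O=C1C(=[#6])SC(=S)N1
quinone_para	O=C1C=CC(=O)C=C1
quinone_ortho	O=C1C(=O)C=CC=C1
catechol	[OX2H]c1ccccc1[OX2H]
hydroxyphenyl_hydrazone	[OX2H]c1ccccc1C=NN
alkylidene_barbiturate	[#6]=C1C(=O)NC(=O)NC1=O
isothiazolone	O=C1C=CSN1
aryl_azo	cN=Nc
anil_di_alk	Nc1ccc(N=C)cc1
gewald_aminothiophene	Nc1sccc1C=O
ene_one_ene	C=CC(=O)C=C
imine_imine	C=NN=C
thiourea_enamine	SC(=N)N=C
beta_keto_anhydride	O=C1OC(=O)C(=C)C1
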
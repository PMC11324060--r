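name	smiles	sps	nsps
aspirin	CC(=O)Oc1ccccc1C(=O)O	121	9.307692307692308
paracetamol	CC(=O)Nc1ccc(cc1)O	101	9.181818181818182
ibuprofen	CC(Cc1ccc(cc1)C(C(=O)O)C)C	192	12.8
naproxen	COc1ccc2c(c1)ccc(c2)C(C(=O)O)C	210	12.352941176470589
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C	155	11.071428571428571
nicotine	CN1CCCC1c1cccnc1	295	24.583333333333332
atenolol	OC(COc1ccc(cc1)CC(=O)N)CNC(C)C	236	12.421052631578947
warfarin	CC(=O)CC(c1c(=O)oc2c(c1O)cccc2)c1ccccc1	281	12.217391304347826
sulfamethoxazole	Nc1ccc(cc1)S(=O)(=O)Nc1noc(c1)C	193	11.352941176470589
omeprazole	COc1ccc2c(c1)nc([nH]2)S(=O)Cc1ncc(c(c1C)OC)C	296	12.333333333333334
diazepam	Clc1ccc2c(c1)C(=NCC(=O)N2C)c1ccccc1	292	14.6
fluoxetine	CNCCC(c1ccccc1)Oc1ccc(cc1)C(F)(F)F	284	12.909090909090908
metformin	CN(C(=N)NC(=N)N)C	74	8.222222222222221
chloroquine	CCN(CCCC(Nc1ccnc2c1ccc(c2)Cl)C)CC	281	12.772727272727273
penicillinG	O=C(Cc1ccccc1)NC1C(=O)N2C1SC(C2C(=O)O)(C)C	644	28.0
estradiol	Oc1ccc2c(c1)CCC1C2CCC2(C1CCC2O)C	854	42.7
cholesterol	CC(CCCC(C1CCC2C1(C)CCC1C2CC=C2C1(C)CCC(C2)O)C)C	1303	46.535714285714285
citalopram	N#Cc1ccc2c(c1)COC2(CCCN(C)C)c1ccc(cc1)F	463	19.291666666666668
lidocaine	CCN(CC(=O)Nc1c(C)cccc1C)CC	181	10.647058823529411
oseltamivir	CCOC(=O)C1=CC(C(C(C1)N)NC(=O)C)OC(CC)CC	546	24.818181818181817
atorvastatin	OC(CC(CC(=O)O)O)CCn1c(C(C)C)c(c(c1c1ccc(cc1)F)c1ccccc1)C(=O)Nc1ccccc1	522	12.731707317073171
celecoxib	Cc1ccc(cc1)c1cc(nn1c1ccc(cc1)S(=O)(=O)N)C(F)(F)F	321	12.346153846153847
tamoxifen	CCC(=C(c1ccccc1)c1ccc(cc1)OCCN(C)C)c1ccc(cc1)OC	357	11.9
tryptophan	OC(=O)C(Cc1c[nH]c2c1cccc2)N	193	12.866666666666667
artemisinin_like	O=C1OC2OC3(C)CCC4C2(C(C1C)CCC4C)OO3	1155	57.75
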
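id	full_name	family	formula	mw	cmc_mM	smiles	monomer_volume_A3	volume_source	reference	aliases	color
DDM	n-Dodecyl-beta-D-maltopyranoside	maltoside	C24H46O11	510.62	0.17	CCCCCCCCCCCCOC1OC(CO)C(OC2OC(CO)C(O)C(O)C2O)C(O)C1O	495.73	additive_estimate	Anatrace D310 product data	beta-DDM|dodecyl maltoside|lauryl maltoside	#33A02C
DM	n-Decyl-beta-D-maltopyranoside	maltoside	C22H42O11	482.56	1.8	CCCCCCCCCCOC1OC(CO)C(OC2OC(CO)C(O)C(O)C2O)C(O)C1O	461.13	additive_estimate	Anatrace D322 product data	decyl maltoside	#33A02C
OG	n-Octyl-beta-D-glucopyranoside	glucoside	C14H28O6	292.37	19	CCCCCCCCOC1OC(CO)C(O)C(O)C1O	291.14	additive_estimate	Anatrace O311 product data	beta-OG|octyl glucoside	#B2DF8A
NG	n-Nonyl-beta-D-glucopyranoside	glucoside	C15H30O6	306.40	6.5	CCCCCCCCCOC1OC(CO)C(O)C(O)C1O	308.44	additive_estimate	Anatrace N324 product data	nonyl glucoside	#B2DF8A
LMNG	Lauryl maltose neopentyl glycol	neopentyl glycol	C47H88O22	1005.19	0.01	CCCCCCCCCCC(CCCCCCCCCC)(COC1OC(CO)C(OC2OC(CO)C(O)C(O)C2O)C(O)C1O)COC3OC(CO)C(OC4OC(CO)C(O)C(O)C4O)C(O)C3O	965.60	additive_estimate	Anatrace NG310 product data	MNG-3|lauryl maltose neopentyl glycol	#FB9A99
DMNG	Decyl maltose neopentyl glycol	neopentyl glycol	C43H80O22	949.08	0.036	CCCCCCCCC(CCCCCCCC)(COC1OC(CO)C(OC2OC(CO)C(O)C(O)C2O)C(O)C1O)COC3OC(CO)C(OC4OC(CO)C(O)C(O)C4O)C(O)C3O	896.40	additive_estimate	Anatrace NG322 product data	MNG-2|decyl maltose neopentyl glycol	#FB9A99
CHS	Cholesteryl hemisuccinate	cholesterol derivative	C31H50O4	486.73	NA	CC(C)CCCC(C)C1CCC2C1(C)CCC3C2CC=C4CC(CCC34C)OC(=O)CCC(O)=O	522.66	additive_estimate	Sigma C6512 product data	cholesteryl hemisuccinate	#FDBF6F
FC-12	n-Dodecylphosphocholine (Fos-choline-12)	fos-choline	C17H38NO4P	351.46	1.5	CCCCCCCCCCCCOP([O-])(=O)OCC[N+](C)(C)C	369.09	additive_estimate	Anatrace F308 product data	FC12|fos-choline-12|DPC|dodecylphosphocholine	#CAB2D6
LDAO	n-Dodecyl-N,N-dimethylamine-N-oxide	amine oxide	C14H31NO	229.40	1	CCCCCCCCCCCC[N+](C)(C)[O-]	270.55	additive_estimate	Anatrace D360 product data	DDAO|lauryldimethylamine oxide	#A6CEE3
DDTM	n-Dodecyl-beta-D-thiomaltopyranoside	thio-derivative	C24H46O10S	526.68	0.05	CCCCCCCCCCCCSC1OC(CO)C(OC2OC(CO)C(O)C(O)C2O)C(O)C1O	505.45	additive_estimate	Anatrace T315 product data	thio-DDM|dodecyl thiomaltoside	#B15928
OTG	n-Octyl-beta-D-thioglucopyranoside	thio-derivative	C14H28O5S	308.43	9	CCCCCCCCSC1OC(CO)C(O)C(O)C1O	300.86	additive_estimate	Anatrace O314 product data	octyl thioglucoside	#B15928
CHOLATE	Sodium cholate	bile salt	C24H39NaO5	430.55	9.5	CC(CCC(O)=O)C1CCC2(C)C1C(O)CC3C2CCC4(C)C3CC(O)CC4O	415.63	additive_estimate	Sigma C1254 product data; volume from the cholic acid composition	sodium cholate|NaC|cholic acid sodium salt	#E31A1C
POPC	1-Palmitoyl-2-oleoyl-sn-glycero-3-phosphocholine	lipid	C42H82NO8P	760.08	NA	CCCCCCCCCCCCCCCC(=O)OCC(COP([O-])(=O)OCC[N+](C)(C)C)OC(=O)CCCCCCCC=CCCCCCCCC	828.83	additive_estimate	Avanti 850457 product data	palmitoyl-oleoyl-phosphatidylcholine	#FFD92F
DMPC	1,2-Dimyristoyl-sn-glycero-3-phosphocholine	lipid	C36H72NO8P	677.93	NA	CCCCCCCCCCCCCC(=O)OCC(COP([O-])(=O)OCC[N+](C)(C)C)OC(=O)CCCCCCCCCCCCC	727.67	additive_estimate	Avanti 850345 product data	dimyristoyl-phosphatidylcholine	#FFD92F
A8-35	Amphipol A8-35	amphipol	poly(acrylate/octylamide/isopropylamide), ~35 units	4300.00	NA	NA	5783.79	curated	Tribet et al. amphipol literature; volume from specific volume 0.81 mL/g at MW 4300	A835|amphipol	#6A3D9A
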
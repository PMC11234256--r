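protein	gene	fold_enrichment	p_value	q_value
Procollagen-lysine,2-oxoglutarate 5-dioxygenase 2	PLOD2	1.95	0.0014	0.0181
Protein disulfide-isomerase	P4HB	1.67	0.0004	0.0101
Prolyl 3-hydroxylase 1	P3H1	1.55	0.0352	0.1486
Cartilage-associated protein	CRTAP	1.53	0.0328	0.1486
Fibronectin	FN1	1.48	0.0397	0.1486
Peptidyl-prolyl cis-trans isomerase FKBP10	FKBP10	1.45	0.0450	0.1486
Serpin H1	SERPINH1	1.45	0.1294	0.2847
Peptidyl-prolyl cis-trans isomerase B	PPIB	1.41	0.0324	0.1486
Prolyl 4-hydroxylase subunit alpha-1	P4HA1	1.41	0.0947	0.2777
Protein canopy homolog 2	CNPY2	1.36	0.3609	0.4793
Peptidyl-prolyl cis-trans isomerase FKBP9	FKBP9	1.36	0.1174	0.2847
Glucosidase 2 subunit beta	PRKCSH	1.32	0.1252	0.2847
Prolyl 4-hydroxylase subunit alpha-2	P4HA2	1.31	0.1772	0.3340
Calumenin	CALU	1.31	0.1904	0.3352
Procollagen-lysine,2-oxoglutarate 5-dioxygenase 1	PLOD1	1.29	0.2534	0.3935
Calreticulin	CALR	1.28	0.0116	0.1021
Multifunctional procollagen lysine hydroxylase and glycosyltransferase LH3	PLOD3	1.24	0.3631	0.4793
Procollagen galactosyltransferase 1	COLGALT1	1.24	0.3873	0.4869
Cytoskeleton-associated protein 4	CKAP4	1.17	0.4509	0.5411
Thioredoxin domain-containing protein 5	TXNDC5	1.14	0.6372	0.6887
Endoplasmic reticulum chaperone BiP	HSPA5	1.13	0.1698	0.3340
Protein disulfide-isomerase A3	PDIA3	1.13	0.2887	0.4233
Endoplasmin	HSP90B1	1.13	0.2434	0.3935
Protein ERGIC-53	LMAN1	1.11	0.6354	0.6887
Protein disulfide-isomerase A4	PDIA4	1.09	0.6521	0.6887
Protein disulfide-isomerase A6	PDIA6	1.01	0.9746	0.9896
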
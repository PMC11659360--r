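region_id	structure_id	structure_name	ghsr	cnr1	double	pct_vs_ghsr	pct_vs_cnr1	nt_GABA	nt_GABA-Glyc	nt_Glut-GABA	nt_Glut	nt_Chol	nt_Dopa
HPF	CA1	Field CA1	2500	212101	2407	96.3	1.1	0	0	0	100	0	0
HPF	CA3	Field CA3	2801	70381	1320	47.1	1.9	1	0	0	99	0	0
HPF	DG	Dentate gyrus	3805	51506	1133	29.8	2.2	0	0	0	100	0	0
CTXsp	BLA	Basolateral amygdalar nucleus	678	47985	629	92.7	1.3	0	0	0	100	0	0
CTXsp	PA	Posterior amygdalar nucleus	468	26537	453	96.8	1.7	0	0	0	100	0	0
STR	MEA	Medial amygdalar nucleus	1693	43102	800	47.3	1.9	13	0	0	87	0	0
PAL	BST	Bed nuclei of the stria terminalis	647	22080	441	68.1	2.0	75	0	0	25	0	0
HY	ARH	Arcuate hypothalamic nucleus	4437	7648	1247	28.1	16.3	76	0	18	1	2	3
HY	DMH	Dorsomedial nucleus of the hypothalamus	634	8990	412	65.0	4.6	64	0	0	33	3	0
HY	AHN	Anterior hypothalamic nucleus	662	23413	458	69.2	2.0	44	0	0	56	0	0
HY	MM	Medial mammillary nucleus	1929	7144	431	22.4	6.0	0	0	3	97	0	0
HY	MPN	Medial preoptic nucleus	602	15675	471	78.3	3.0	58	0	0	42	0	0
HY	PMv	Ventral premammillary nucleus	549	8154	333	60.7	4.1	0	0	0	100	0	0
HY	VMH	Ventromedial hypothalamic nucleus	1004	29262	729	72.6	2.5	3	0	0	93	3	1
HY	PH	Posterior hypothalamic nucleus	627	17403	384	61.2	2.2	20	0	0	73	0	7
HY	LHA	Lateral hypothalamic area	468	23427	341	73.0	1.5	67	0	0	30	0	4
HY	ZI	Zona incerta	1274	41399	904	71.0	2.2	100	0	0	0	0	0
MB	SCs	Superior colliculus, sensory related	551	19710	348	63.0	1.8	93	0	0	7	0	0
MB	SNr	Substantia nigra, reticular part	1079	9846	580	53.8	5.9	100	0	0	0	0	0
MB	VTA	Ventral tegmental area	2355	2167	332	14.1	15.3	39	0	0	0	0	61
MB	MRN	Midbrain reticular nucleus	2011	36820	1408	70.0	3.8	48	3	5	45	0	0
MB	SCm	Superior colliculus, motor related	1973	79564	1586	80.4	2.0	66	0	0	34	0	0
MB	PAG	Periaqueductal gray	3663	97288	2669	72.9	2.7	52	3	1	40	0	3
MB	PPN	Pedunculopontine nucleus	729	10680	613	84.1	5.7	9	2	0	83	2	5
P	PB	Parabrachial nucleus	803	14388	708	88.2	4.9	3	0	3	88	0	6
P	PRNc	Pontine reticular nucleus, caudal part	1120	18550	856	76.4	4.6	0	69	0	31	0	0
P	PRNr	Pontine reticular nucleus	1004	23325	824	82.1	3.5	8	49	13	31	0	0
MY	AP	Area postrema	431	1618	377	87.5	23.3	0	100	0	0	0	0
MY	NTS	Nucleus of the solitary tract	795	14017	778	97.8	5.5	0	71	0	20	9	0
MY	GRN	Gigantocellular reticular nucleus	845	11060	474	56.2	4.3	0	49	0	51	0	0
MY	IRN	Intermediate reticular nucleus	759	14177	538	70.9	3.8	0	62	0	38	0	0
MY	PARN	Parvicellular reticular nucleus	769	16695	618	80.3	3.7	0	74	0	25	2	0
MY	MV	Medial vestibular nucleus	1438	10581	450	31.3	4.3	2	61	0	37	0	0
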
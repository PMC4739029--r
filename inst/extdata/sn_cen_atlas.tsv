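index	network	abbrev	x	y	z	area_name
1	SN	aIns_L	-31	21	-2	Anterior insula
2	SN	aIns_R	39	19	-3	Anterior insula
3	SN	pIns_L	-40	-4	2	Posterior insula
4	SN	pIns_R	42	-6	0	Posterior insula
5	SN	dACC	2	22	28	Dorsal anterior cingulate cortex
6	SN	MFG_L	-37	42	25	Middle frontal gyrus
7	SN	MFG_R	34	45	22	Middle frontal gyrus
8	SN	SMG_L	-59	-35	29	Supramarginal gyrus
9	SN	SMG_R	58	-37	33	Supramarginal gyrus
10	CEN	IPS_L	-23	-70	46	Left intraparietal sulcus
11	CEN	IPS_R	25	-62	53	Left intraparietal sulcus
12	CEN	iPL_L	-42	-48	51	Inferior parietal lobule
13	CEN	iPL_R	57	-36	54	Inferior parietal lobule
14	CEN	vIPS_L	-15	-90	24	Ventral parietal sulcus
15	CEN	vIPS_R	35	-85	27	Ventral parietal sulcus
16	CEN	FEF_L	-24	-15	66	Frontal eye field
17	CEN	FEF_R	28	-10	58	Frontal eye field
18	CEN	IPCL	-55	-2	38	Inferior precentral lobule
19	CEN	SMA	-2	-2	55	Supplementary motor area
20	CEN	DLPFC_L	-40	39	30	Dorsolateral prefrontal cortex
21	CEN	DLPFC_R	38	41	26	Dorsolateral prefrontal cortex
22	CEN	VOC_L	-47	-71	-8	Ventral occipital lobe
23	CEN	VOC_R	55	-64	-13	Ventral occipital lobe
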
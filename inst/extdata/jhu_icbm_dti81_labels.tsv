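index	roi	name	hemisphere	tract
1	MCP	Middle cerebellar peduncle	M	MCP
2	PCT	Pontine crossing tract	M	PCT
3	GCC	Genu of corpus callosum	M	GCC
4	BCC	Body of corpus callosum	M	BCC
5	SCC	Splenium of corpus callosum	M	SCC
6	FX	Fornix (column and body)	M	FX
7	CST-R	Corticospinal tract R	R	CST
8	CST-L	Corticospinal tract L	L	CST
9	ML-R	Medial lemniscus R	R	ML
10	ML-L	Medial lemniscus L	L	ML
11	ICP-R	Inferior cerebellar peduncle R	R	ICP
12	ICP-L	Inferior cerebellar peduncle L	L	ICP
13	SCP-R	Superior cerebellar peduncle R	R	SCP
14	SCP-L	Superior cerebellar peduncle L	L	SCP
15	CP-R	Cerebral peduncle R	R	CP
16	CP-L	Cerebral peduncle L	L	CP
17	ALIC-R	Anterior limb of internal capsule R	R	ALIC
18	ALIC-L	Anterior limb of internal capsule L	L	ALIC
19	PLIC-R	Posterior limb of internal capsule R	R	PLIC
20	PLIC-L	Posterior limb of internal capsule L	L	PLIC
21	RLIC-R	Retrolenticular part of internal capsule R	R	RLIC
22	RLIC-L	Retrolenticular part of internal capsule L	L	RLIC
23	ACR-R	Anterior corona radiata R	R	ACR
24	ACR-L	Anterior corona radiata L	L	ACR
25	SCR-R	Superior corona radiata R	R	SCR
26	SCR-L	Superior corona radiata L	L	SCR
27	PCR-R	Posterior corona radiata R	R	PCR
28	PCR-L	Posterior corona radiata L	L	PCR
29	PTR-R	Posterior thalamic radiation R	R	PTR
30	PTR-L	Posterior thalamic radiation L	L	PTR
31	SS-R	Sagittal stratum R	R	SS
32	SS-L	Sagittal stratum L	L	SS
33	EC-R	External capsule R	R	EC
34	EC-L	External capsule L	L	EC
35	CGC-R	Cingulum (cingulate gyrus) R	R	CGC
36	CGC-L	Cingulum (cingulate gyrus) L	L	CGC
37	CGH-R	Cingulum (hippocampus) R	R	CGH
38	CGH-L	Cingulum (hippocampus) L	L	CGH
39	FXST-R	Fornix (cres) / Stria terminalis R	R	FXST
40	FXST-L	Fornix (cres) / Stria terminalis L	L	FXST
41	SLF-R	Superior longitudinal fasciculus R	R	SLF
42	SLF-L	Superior longitudinal fasciculus L	L	SLF
43	SFO-R	Superior fronto-occipital fasciculus R	R	SFO
44	SFO-L	Superior fronto-occipital fasciculus L	L	SFO
45	UNC-R	Uncinate fasciculus R	R	UNC
46	UNC-L	Uncinate fasciculus L	L	UNC
47	TAP-R	Tapetum R	R	TAP
48	TAP-L	Tapetum L	L	TAP
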
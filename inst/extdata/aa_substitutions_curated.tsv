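gene	contig	chromosome	aa_position	region	ref_aa	alt1_aa	alt2_aa	outgroup_aa	wild_aa	mutant_aa	mutant2_aa	freq_wild	freq_mutant	freq_mutant2	label
GI	contig15400	Chr05K	155	Exon7	E	K	NA	E	E	K	NA	91.59	8.41	NA	Con
GI	contig15400	Chr05K	175	Exon7	S	Y	NA	S	S	Y	NA	80.32	19.68	NA	Non Con
GI	contig15400	Chr05K	177	Exon7	G	D	NA	D	D	G	NA	32.80	67.20	NA	Non Con
GI	contig15400	Chr05K	180	Exon7	G	R	NA	G	G	R	NA	92.79	7.21	NA	Non Con
GI	contig15400	Chr05K	234	Exon9	C	F	Y	C	C	F	Y	79.82	19.59	0.58	Non Con
GI	contig01489	Chr05N	63	Exon5	W	S	NA	S	S	W	NA	37.50	62.50	NA	Non Con
GI	contig01489	Chr05N	185	Exon7	R	Q	NA	R	R	Q	NA	65.84	34.16	NA	Con
GI	contig01489	Chr05N	960	Exon14	F	L	NA	L	L	F	NA	35.83	64.17	NA	Non Con
PHYB	contig13571	Chr09N	661	Exon2	S	C	NA	S	S	C	NA	63.64	36.36	NA	Non Con
PHYB	contig13571	Chr09N	702	Exon2	V	I	NA	V	V	I	NA	79.13	20.87	NA	Con
PHYB	contig13571	Chr09N	713	Exon2	Y	D	NA	D	D	Y	NA	50.30	49.70	NA	Non Con
HD1	contig03275	Chr04K	11	Exon1	E	M	NA	E	E	M	NA	85.98	14.02	NA	Non Con
HD1	contig03275	Chr04K	32	Exon1	A	T	NA	A	A	T	NA	94.56	5.44	NA	Non Con
HD1	contig03275	Chr04K	35	Exon1	G	S	NA	S	S	G	NA	60.63	39.37	NA	Non Con
PGM	contig17299	Chr09K	351	Exon6	A	V	NA	A	A	V	NA	73.21	26.79	NA	Non Con
TB1	contig06045	Chr09K	57	Exon1	G	D	NA	G	G	D	NA	91.61	8.39	NA	Non Con
TB1	contig06045	Chr09K	213	Exon1	G	D	NA	G	G	D	NA	89.76	10.24	NA	Non Con
TB1	contig06045	Chr09K	337	Exon1	I	V	NA	L	I	V	NA	56.64	43.36	NA	Con
TB1	contig76312	Chr09N	51	Exon1	H	Y	NA	H	H	Y	NA	88.06	11.94	NA	Con
TB1	contig76312	Chr09N	89	Exon1	A	P	NA	A	A	P	NA	92.42	7.58	NA	Non Con
TB1	contig76312	Chr09N	137	Exon1	S	P	NA	S	S	P	NA	92.77	7.23	NA	Non Con
TB1	contig76312	Chr09N	193	Exon1	I	V	NA	V	V	I	NA	60.26	39.74	NA	Con
TB1	contig76312	Chr09N	321	Exon1	N	S	NA	N	N	S	NA	91.87	8.13	NA	Con
PHYC	contig03093	Chr09N	422	Exon1	V	L	NA	L	L	V	NA	45.71	54.29	NA	Con
PHYC	contig03093	Chr09N	966	Exon3	E	V	NA	V	V	E	NA	42.90	57.10	NA	Non Con
PHYC	contig03093	Chr09N	1029	Exon3	P	A	NA	P	P	A	NA	81.03	18.97	NA	Non Con
PHYC	contig03093	Chr09N	1031	Exon3	K	E	NA	K	K	E	NA	76.66	23.34	NA	Con
PHYC	contig03093	Chr09N	1041	Exon3	K	N	NA	K	K	N	NA	83.44	16.56	NA	Non Con
PHYC	contig03093	Chr09N	1069	Exon1	L	W	NA	L	L	W	NA	94.26	5.74	NA	Non Con
PHYC	contig03093	Chr09N	1104	Exon1	L	H	NA	L	L	H	NA	67.70	32.30	NA	Non Con
VRN3	contig07490	Chr03N	238	Exon2	E	D	NA	E	E	D	NA	89.78	10.22	NA	Con
VRN3	contig07490	Chr03N	286	Exon3	L	M	NA	L	L	M	NA	93.11	6.89	NA	Con
VRN3	contig07490	Chr03N	295	Exon3	T	A	NA	T	T	A	NA	90.10	9.90	NA	Non Con
VRN3	contig07490	Chr03N	412	Exon4	P	R	NA	P	P	R	NA	91.53	8.47	NA	Non Con
VRN3	contig07490	Chr03N	493	Exon4	L	S	NA	S	S	L	NA	84.26	15.74	NA	Non Con
VRN3	contig07490	Chr03N	511	Exon4	N	K	NA	N	N	K	NA	93.63	6.37	NA	Non Con
VRN3	contig07490	Chr03N	600	Exon4	G	V	NA	E	G	V	NA	88.59	11.41	NA	Non Con
VRN3	contig16433	Chr03K	144	Exon2	P	A	NA	P	P	A	NA	90.45	9.55	NA	Non Con
VRN3	contig16433	Chr03K	398	Exon4	V	I	NA	A	V	I	NA	93.98	6.02	NA	Con
VRN3	contig16433	Chr03K	409	Exon4	S	N	NA	S	S	N	NA	89.42	10.58	NA	Con
VRN3	contig16433	Chr03K	450	Exon4	D	G	NA	G	G	D	NA	43.61	56.39	NA	Non Con
VRN3	contig16433	Chr03K	569	Exon4	Q	E	NA	R	Q	E	NA	88.36	11.64	NA	Con
VRN3	contig16433	Chr03K	682	Exon4	L	Q	NA	Q	Q	L	NA	28.61	71.39	NA	Non Con
DW3	contig26301	Chr06K	672	Exon3	E	G	NA	E	E	G	NA	94.29	5.71	NA	Non Con
DW3	contig26301	Chr06K	751	Exon3	M	V	NA	M	M	V	NA	21.22	78.78	NA	Con
DW3	contig117938	Chr06N	713	Exon3	I	M	NA	M	M	I	NA	87.84	12.16	NA	Con
DW3	contig26301	Chr06N	897	Exon3	I	V	NA	V	V	I	NA	82.96	17.04	NA	Con
DW3	contig117938	Chr06N	872	Exon3	T	A	S	A	A	T	S	78.04	21.96	0.30	Non Con
FLD	contig01920	Chr07N	511	Exon1	S	G	NA	G	G	S	NA	76.70	23.30	NA	Non Con
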
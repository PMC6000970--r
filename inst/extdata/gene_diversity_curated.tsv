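gene	contig	chromosome	n_samples	n_sites	coding_length	s_tot	non_cod	syn	con	non_con	d	pi	pi_sd	theta_w	theta_sd	h	hd	hd_sd	tajima_d
PHYC	contig03093	Chr09N	353	3224	2279	20	7	6	2	5	0.620	1.68	0.04	0.87	0.25	91	0.963	0.002	0.362
TE	contig99597	Chr05K	351	2088	278	21	21	0	0	0	1.006	3.43	0.08	1.40	0.31	84	0.883	0.010	0.138
TE	contig04674	Chr05N	334	2088	278	21	20	1	0	0	1.006	3.78	0.09	1.58	0.34	110	0.959	0.003	0.316
VRN3	contig07490	Chr03N	337	2258	1771	12	1	4	2	5	0.531	1.30	0.05	0.74	0.21	22	0.759	0.013	0.723
VRN3	contig16433	Chr03K	356	2258	1773	10	3	1	3	3	0.443	0.95	0.03	0.62	0.19	30	0.728	0.016	0.620
DW3	contig26301	Chr06K	327	2207	2207	5	2	0	2	1	0.227	0.56	0.02	0.32	0.14	10	0.629	0.018	1.267
DW3	contig117938	Chr06N	337	2198	2198	4	2	0	1	1	0.182	0.55	0.02	0.25	0.13	14	0.714	0.010	0.793
FLD	contig102960	Chr07K	346	2329	1395	3	2	1	0	0	0.129	0.10	0.01	0.18	0.10	5	0.207	0.020	-0.588
FLD	contig01920	Chr07N	339	2330	1395	1	0	0	0	1	0.043	0.15	0.01	0.06	0.06	2	0.346	0.017	1.253
GI	contig15400	Chr05K	342	3456	1185	20	13	2	1	4	0.608	1.71	0.06	0.81	0.18	83	0.904	0.006	-0.264
GI	contig01489	Chr05N	312	3464	1185	10	7	0	1	2	0.289	1.05	0.03	0.40	0.13	22	0.757	0.013	1.655
FLT	contig09545	Chr07K	365	1826	195	17	17	0	0	0	0.931	1.97	0.05	1.30	0.31	64	0.931	0.005	-0.103
FLT	contig08422	Chr07N	339	2181	195	21	21	0	0	0	0.963	2.85	0.04	1.34	0.29	62	0.899	0.006	0.630
PHYB	contig13571	Chr09N	350	3198	2758	4	1	0	1	2	0.125	0.55	0.01	0.17	0.09	7	0.697	0.009	3.265
PHYB	contig21054	Chr09K	342	3194	2758	7	6	1	0	0	0.219	0.49	0.01	0.30	0.12	12	0.666	0.012	0.771
HD1	contig03275	Chr04K	306	2220	1104	7	2	2	0	3	0.360	0.93	0.44	0.44	0.17	8	0.776	0.008	2.082
HD1	contig05584	Chr04N	363	2140	1113	17	17	0	0	0	0.280	1.66	0.04	1.11	0.27	30	0.901	0.005	-0.142
PGM	contig17299	Chr09K	343	3120	1634	8	5	2	0	1	0.256	0.59	0.36	0.36	0.13	28	0.848	0.008	1.270
PGM	contig200892	Chr09N	315	696	391	7	4	3	0	0	1.006	3.30	0.05	1.40	0.53	13	0.780	0.007	1.328
TB1	contig06045	Chr09K	339	2428	1109	10	2	5	1	2	0.412	1.42	0.03	0.59	0.21	38	0.817	0.010	1.625
TB1	contig76312	Chr09N	314	2597	1115	26	16	5	3	2	1.001	2.53	0.07	1.41	0.37	84	0.926	0.005	0.037
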
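grouping	source	df	SS	MS	est_var	pct
latitude_bin	Among latitude bins	12	6207.75	517.31	8.09	15
latitude_bin	Among individuals	349	29954.89	85.83	39.32	72
latitude_bin	Within individual	362	2605.00	7.20	7.20	13
latitude_bin	Total	723	38767.64	NA	54.60	100
accession	Among accessions	35	12965.07	370.43	14.92	28
accession	Among individuals	326	23197.37	71.16	31.98	59
accession	Within individual	362	2605.00	7.20	7.20	13
accession	Total	723	38767.44	NA	54.10	100
subpopulation	Among subpopulations	2	8818.28	4409.14	22.69	37
subpopulation	Among individuals	306	22088.76	72.19	32.61	52
subpopulation	Within individual	309	2151.00	6.96	6.96	11
subpopulation	Total	617	33058.04	NA	62.27	100
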
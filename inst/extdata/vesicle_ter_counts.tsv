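strain	replicon	ter_start	ter_end	total	ter	mean	median	std	enrichment	accession
Prochlorococcus sp. Med4	NC_005072.1	826000	832000	1368548	92377	3050	0	13221	92377	SRR1013844
Prochlorococcus sp. Med4	NC_005072.1	826000	832000	2729515	186179	16381	0	60827	186179	SRR1013875
Pseudomonas aeruginosa	NC_002516.2	2440067	2446067	55750742	54594	35740	49237	26894	1	SRR1654902
Vibrio cholerae Chr 1	NC_009457.1	1126240	1132240	792045	11395	1170	1234	1133	9	SRR10387914
Vibrio cholerae Chr 2	NC_009456.1	564632	570632	4869589	5046	8735	540	34823	9	SRR10387914
Dinoroseobacter shibae	NC_009952.1	1613200	1620200	6129709	234919	11238	3122	32204	75	SAMEA114558114
Dinoroseobacter shibae	NC_009952.1	1613200	1620200	5333124	191321	7894	3640	18346	53	SAMEA114558116
Escherichia coli BW25113	NZ_CP009273.1	1582052	1588052	1725436	28376	1626	2051	1103	14	SAMEA113533507
Escherichia coli BW25113	NZ_CP009273.1	1582052	1588052	1237778	100698	1015	1258	813	80	SAMEA113533508
Escherichia coli BW25113	NZ_CP009273.1	1582052	1588052	1229730	79686	1388	1320	2038	60	SAMEA113533509
Escherichia coli BW25113 dxerC	NZ_CP009273.1	1582052	1588052	2589912	94403	4828	2644	12692	36	SAMEA113533510
Escherichia coli BW25113 dxerC	NZ_CP009273.1	1582052	1588052	2593008	98750	2937	2609	4860	38	SAMEA113533511
Escherichia coli BW25113 dxerD	NZ_CP009273.1	1582052	1588052	2191086	69473	2202	2057	3079	34	SAMEA113533512
Escherichia coli BW25113 dxerD	NZ_CP009273.1	1582052	1588052	3204824	178388	6230	2631	18814	68	SAMEA113533513
Escherichia coli BW25113 dxerD	NZ_CP009273.1	1582052	1588052	2544678	182057	5042	1598	16863	114	SAMEA113533514
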
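layer	Distance	Repl	Richness	LCrepl	LCrepl_sig	LCrich	LCrich_sig	OTUs	Coverage
0-1	NA	NA	NA	0.083	***	0.039		1787	0.825
1-2	0.683	0.600	0.083	0.086	***	0.001		1566	0.867
2-3	0.668	0.662	0.006	0.068		0.050		1724	0.828
3-4	0.688	0.659	0.029	0.057		0.079		1870	0.818
4-5	0.735	0.733	0.003	0.064		0.052		1759	0.833
5-6	0.739	0.709	0.030	0.070	*	0.024		1625	0.859
6-7	0.761	0.722	0.040	0.069		0.019		1611	0.860
7-8	0.780	0.751	0.029	0.066		0.030		1709	0.841
8-9	0.822	0.749	0.072	0.071	**	0.010		1567	0.861
9-10	0.824	0.753	0.071	0.071	**	0.010		1557	0.863
10-14	0.860	0.782	0.078	0.074	***	0.011		1518	0.853
14-18	0.902	0.720	0.183	0.063		0.075		1268	0.880
18-22	0.920	0.715	0.206	0.061		0.113		1242	0.891
22-26	0.930	0.689	0.241	0.056		0.183		1087	0.905
26-30	0.934	0.649	0.285	0.041		0.304	*	1019	0.903
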
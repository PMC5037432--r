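gene	variant_id	phenotype	model	n_studies	n_cases	n_controls	or	ci_low	ci_high	p	i2	i2_low	i2_high	power	bfdp	venice
NOD2	rs2066844	CD	dominant	16	1984	4179	2.23	1.88	2.64	4.77E-20	46	2	82	1.00	0.000	ABB
NOD2	rs2066844	CD	recessive	12	1984	4179	4.14	2.18	7.89	1.54E-05	0	0	49	0.99	0.035	AAB
NOD2	rs2066844	CD	additive1	16	1984	4179	2.11	1.77	2.52	9.81E-17	36	0	78	1.00	0.000	ABB
NOD2	rs2066844	CD	additive2	12	1984	4179	4.44	2.34	8.43	5.26E-06	0	0	54	0.99	0.016	AAB
NOD2	rs2066845	CD	dominant	16	2059	4274	3.21	2.25	4.60	1.61E-10	53	10	84	1.00	0.000	ACB
NOD2	rs2066845	CD	recessive	11	2059	4274	8.64	2.80	26.69	1.77E-04	0	0	0	1.00	0.465	AAB
NOD2	rs2066845	CD	additive1	16	2059	4274	3.02	2.42	3.76	5.04E-23	50	6	82	1.00	0.000	ABB
NOD2	rs2066845	CD	additive2	11	2059	4274	9.18	2.99	28.22	1.09E-04	0	0	0	1.00	0.405	AAB
NOD2	rs2066847	CD	dominant	16	1980	4234	5.78	3.67	9.11	4.12E-14	77	58	92	1.00	0.000	ACB
NOD2	rs2066847	CD	recessive	10	1980	4234	91.00	25.07	330.27	6.97E-12	0	0	57	1.00	0.000	AAB
NOD2	rs2066847	CD	additive1	16	1980	4234	5.03	3.34	7.59	1.34E-14	70	46	89	1.00	0.000	ACB
NOD2	rs2066847	CD	additive2	10	1980	4234	105.94	30.65	366.14	1.72E-13	0	0	67	1.00	0.000	AAB
NOD2	rs5743289	CD	dominant	3	376	687	1.48	1.13	1.94	0.004	0	0	0	0.83	0.640	AAB
IL23R	rs11209026	CD	dominant	10	1158	4766	0.32	0.23	0.43	2.10E-13	0	0	50	1.00	0.000	AAB
IL23R	rs11209026	CD	recessive	7	1158	4766	0.97	0.31	3.04	0.952	0	0	32	0.05	0.963	CAB
IL23R	rs11209026	CD	additive1	10	1158	4766	0.33	0.24	0.44	8.29E-13	0	0	51	1.00	0.000	AAB
IL23R	rs11209026	CD	additive2	7	1158	4766	0.88	0.29	2.76	0.823	0	0	30	0.06	0.963	CAB
IL23R	rs7517847	CD	dominant	4	496	1383	0.66	0.53	0.83	3.13E-04	0	0	79	0.95	0.180	AAB
IL23R	rs7517847	CD	recessive	4	496	1383	0.57	0.41	0.79	8.97E-04	49	0	94	0.96	0.262	ABB
IL23R	rs7517847	CD	additive1	4	496	1383	0.73	0.58	0.93	0.010	0	0	41	0.80	0.800	AAB
IL23R	rs7517847	CD	additive2	4	496	1383	0.47	0.32	0.67	4.11E-05	45	0	93	1.00	0.023	ABB
IBD5	rs11739135	CD	dominant	4	536	722	1.24	0.97	1.59	0.082	48	0	98	0.41	0.956	CBB
IBD5	rs11739135	CD	recessive	4	536	722	1.41	1.05	1.89	0.024	28	0	98	0.63	0.862	BBB
IBD5	rs11739135	CD	additive1	4	536	722	1.17	0.90	1.51	0.245	15	0	97	0.23	0.977	CAB
IBD5	rs11739135	CD	additive2	4	536	722	1.55	1.11	2.17	0.011	56	0	99	0.73	0.767	BCB
IBD5	rs12521868	CD	dominant	4	536	731	1.35	1.05	1.73	0.018	0	0	95	0.68	0.856	BAB
IBD5	rs12521868	CD	recessive	4	536	731	1.76	1.31	2.35	1.55E-04	0	0	23	0.97	0.072	AAB
IBD5	rs12521868	CD	additive1	4	536	731	1.20	0.92	1.55	0.178	0	0	94	0.28	0.971	CAB
IBD5	rs12521868	CD	additive2	4	536	731	1.88	1.34	2.62	2.22E-04	0	0	96	0.96	0.101	AAB
IBD5	rs17622208	CD	dominant	3	527	872	1.38	1.05	1.81	0.020	51	0	92	0.83	0.861	ACB
IBD5	rs17622208	CD	recessive	2	527	872	1.28	0.92	1.78	0.140	0	0	0	0.33	0.961	CAB
IBD5	rs17622208	CD	additive1	3	527	872	1.33	1.00	1.78	0.050	53	0	92	0.54	0.930	BCB
IBD5	rs17622208	CD	additive2	2	527	872	1.61	1.09	2.37	0.020	34	0	85	0.64	0.811	BBB
IBD5	rs1050152	CD	dominant	7	757	1534	1.20	0.98	1.47	0.072	0	0	76	0.45	0.959	CAB
IBD5	rs1050152	CD	recessive	7	757	1534	1.48	1.17	1.86	9.91E-04	0	0	79	0.93	0.293	AAB
IBD5	rs1050152	CD	additive1	7	757	1534	1.09	0.88	1.35	0.416	0	0	76	0.13	0.987	CAB
IBD5	rs1050152	CD	additive2	7	757	1534	1.55	1.18	2.02	0.001	0	0	79	0.92	0.360	AAB
IBD5	rs26313667	CD	dominant	5	653	1117	1.40	1.11	1.77	0.005	0	0	83	0.82	0.675	AAB
IBD5	rs26313667	CD	recessive	5	653	1117	1.42	1.13	1.78	0.003	0	0	7	0.87	0.527	AAB
IBD5	rs26313667	CD	additive1	5	653	1117	1.28	1.00	1.64	0.051	0	0	84	0.51	0.934	BAB
IBD5	rs26313667	CD	additive2	5	653	1117	1.68	1.26	2.23	3.67E-04	0	0	67	0.96	0.153	AAB
ATG16L1	rs2241880	CD	dominant	12	1360	6385	0.70	0.62	0.81	3.14E-07	0	0	53	1.00	0.002	AAB
ATG16L1	rs2241880	CD	recessive	12	1360	6385	0.73	0.62	0.87	2.70E-04	0	0	51	0.90	0.225	ACB
ATG16L1	rs2241880	CD	additive1	12	1360	6385	0.74	0.64	0.86	4.14E-05	0	0	33	0.98	0.067	AAB
ATG16L1	rs2241880	CD	additive2	12	1360	6385	0.61	0.51	0.74	2.85E-07	4	0	60	1.00	0.001	AAB
DLG5	rs1248696	CD	dominant	4	427	846	0.79	0.57	1.09	0.148	0	0	94	0.34	0.961	CAB
DLG5	rs1248696	CD	recessive	4	427	846	0.56	0.14	2.26	0.416	0	0	81	0.12	0.955	CAB
DLG5	rs1248696	CD	additive1	4	427	846	0.80	0.57	1.12	0.192	0	0	93	0.27	0.968	CAB
DLG5	rs1248696	CD	additive2	4	427	846	0.55	0.14	2.21	0.397	0	0	82	0.13	0.955	CAB
DLG5	rs2289311	CD	dominant	3	165	750	0.76	0.53	1.10	0.151	19	0	98	0.36	0.958	CAB
DLG5	rs2289311	CD	recessive	3	165	750	0.55	0.29	1.06	0.075	0	0	97	0.50	0.920	BAB
DLG5	rs2289311	CD	additive1	3	165	750	0.84	0.57	1.23	0.371	4	0	98	0.16	0.976	CAB
DLG5	rs2289311	CD	additive2	3	165	750	0.51	0.26	1.01	0.053	0	0	97	0.58	0.954	BAB
PSMG1	rs2836878	CD	dominant	3	425	705	1.06	0.83	1.36	0.623	43	0	98	0.07	0.987	CBB
PSMG1	rs2836878	CD	recessive	3	425	705	0.98	0.33	2.91	0.971	67	0	99	0.05	0.964	CCB
PSMG1	rs2836878	CD	additive1	3	425	705	1.13	0.88	1.46	0.339	0	0	96	0.16	0.982	CAB
PSMG1	rs2836878	CD	additive2	3	425	705	1.10	0.33	3.72	0.872	72	0	99	0.07	0.962	CCB
TNF-a	rs1800629	CD	dominant	5	509	1443	1.98	1.29	3.03	0.002	57	0	96	1.00	0.415	ACB
TNF-a	rs1800629	CD	recessive	4	509	1443	3.79	1.96	7.32	7.52E-05	0	0	95	0.98	0.101	AAB
TNF-a	rs1800629	CD	additive1	5	509	1443	1.91	1.27	2.85	0.002	51	0	95	1.00	0.397	ACB
TNF-a	rs1800629	CD	additive2	4	509	1443	4.75	2.43	9.26	4.86E-06	0	0	96	1.00	0.017	AAB
TNF-a	rs1799724	CD	dominant	3	326	854	0.90	0.67	1.22	0.501	47	0	99	0.10	0.983	CBB
TNF-a	rs1799724	CD	recessive	3	326	854	0.63	0.28	1.41	0.259	0	0	95	0.13	0.955	CAB
TNF-a	rs1799724	CD	additive1	3	326	854	0.94	0.69	1.29	0.718	47	0	99	0.07	0.985	CBB
TNF-a	rs1799724	CD	additive2	3	326	854	0.60	0.26	1.36	0.221	0	0	96	0.15	0.952	CAB
PTPN2	rs2542151	CD	dominant	3	461	2152	1.05	0.83	1.33	0.667	0	0	82	0.07	0.988	CAB
PTPN2	rs2542151	CD	recessive	3	461	2152	1.77	0.88	3.55	0.108	0	0	95	0.42	0.934	CAB
PTPN2	rs2542151	CD	additive1	3	461	2152	1.01	0.79	1.28	0.955	0	0	0	0.05	0.989	CAB
PTPN2	rs2542151	CD	additive2	3	461	2152	1.77	0.88	3.56	0.108	0	0	95	0.42	0.934	CAB
TLR4	rs4986790	CD	dominant	3	214	369	1.54	0.92	2.58	0.100	20	0	97	0.38	0.937	CAB
BSN-MST1	rs9858542	CD	dominant	3	414	679	2.08	1.62	2.68	1.00E-05	13	0	83	1.00	0.030	AAB
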
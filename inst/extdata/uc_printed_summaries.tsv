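gene	variant_id	phenotype	model	n_studies	n_cases	n_controls	or	ci_low	ci_high	p	i2	i2_low	i2_high	power	bfdp	venice
NOD2	rs2066844	UC	dominant	6	590	1512	1.66	1.20	2.28	0.002	34	0	91	0.88	0.427	ABB
NOD2	rs2066844	UC	recessive	4	590	1512	0.96	0.20	4.68	0.960	0	0	77	0.05	0.959	CAB
NOD2	rs2066844	UC	additive1	6	590	1512	1.73	1.25	2.36	8.80E-04	34	0	91	0.88	0.215	ABB
NOD2	rs2066844	UC	additive2	4	590	1512	1.02	0.21	5.00	0.980	0	0	79	0.05	0.959	CAB
NOD2	rs2066845	UC	dominant	6	591	1515	1.14	0.70	1.87	0.600	0	0	87	0.09	0.976	CAB
NOD2	rs2066845	UC	recessive	2	591	1515	3.24	0.17	63.38	0.439	0	0	0	0.30	0.951	CAB
NOD2	rs2066845	UC	additive1	6	591	1515	1.11	0.68	1.84	0.600	0	0	87	0.09	0.976	CAB
NOD2	rs2066845	UC	additive2	2	591	1515	3.06	0.16	57.43	0.455	0	0	0	0.28	0.951	CAB
NOD2	rs2066847	UC	dominant	6	593	1502	1.76	1.11	2.80	0.010	0	0	95	0.74	0.813	BAB
NOD2	rs2066847	UC	additive1	6	593	1502	1.79	1.13	2.84	0.010	0	0	0	0.74	0.785	BAB
IL23R	rs11209026	UC	dominant	3	393	1321	0.55	0.37	0.84	0.005	0	0	83	0.85	0.653	AAB
IL23R	rs11209026	UC	additive1	3	393	1321	0.56	0.37	0.85	0.007	0	0	83	0.84	0.677	AAB
IBD5	rs1050152	UC	dominant	4	353	1056	1.22	0.93	1.61	0.150	0	0	82	0.31	0.968	CAB
IBD5	rs1050152	UC	recessive	4	353	1056	1.40	1.03	1.91	0.030	0	0	90	0.61	0.897	BAB
IBD5	rs1050152	UC	additive1	4	353	1056	1.12	0.84	1.50	0.430	0	0	76	0.12	0.983	CAB
IBD5	rs1050152	UC	additive2	4	353	1056	1.52	1.06	2.17	0.022	0	0	90	0.66	0.848	BAB
IBD5	rs26313667	UC	dominant	4	353	1044	1.30	0.97	1.75	0.081	0	0	66	0.46	0.947	CAB
IBD5	rs26313667	UC	recessive	4	353	1044	1.29	0.97	1.71	0.085	17	0	98	0.44	0.946	CAB
IBD5	rs26313667	UC	additive1	4	353	1044	1.22	0.89	1.67	0.209	0	0	91	0.25	0.971	CAB
IBD5	rs26313667	UC	additive2	4	353	1044	1.49	1.04	2.13	0.031	0	0	87	0.61	0.876	BAB
DLG5	rs1248696	UC	dominant	3	289	800	0.85	0.58	1.24	0.405	0	0	75	0.14	0.970	CAB
DLG5	rs1248696	UC	recessive	3	289	800	0.74	0.16	3.33	0.690	0	0	97	0.06	0.958	CAB
DLG5	rs1248696	UC	additive1	3	289	800	0.86	0.58	1.27	0.450	0	0	62	0.14	0.978	CAB
DLG5	rs1248696	UC	additive2	3	289	800	0.72	0.16	3.24	0.664	0	0	97	0.06	0.958	CAB
TNF-a	rs1800629	UC	dominant	3	235	844	1.81	0.82	3.99	0.143	69	0	99	0.95	0.941	ACB
TNF-a	rs1800629	UC	recessive	3	235	844	3.08	0.99	9.55	0.052	0	0	97	0.74	0.913	BAB
TNF-a	rs1800629	UC	additive1	3	235	844	1.65	1.10	2.47	0.015	61	0	99	0.83	0.802	ACB
TNF-a	rs1800629	UC	additive2	3	235	844	3.34	1.09	10.22	0.035	0	0	98	0.80	0.889	AAB
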
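rank	marker	motif	repeat_count	ta_c	n_alleles	size_min	size_max	he	ho	pic
1	BrPe0032	AT	13	60	7	137	157	0.84	1	0.77
2	BrPe0028	TA	6	55	5	90	110	0.8	0.5	0.72
3	BrPe0024	TC	7	55	4	221	231	0.76	0.7	0.68
4	BrPe0031	TA	9	60	5	134	150	0.77	0.67	0.67
5	BrPe0014	AG	7	57	5	215	227	0.75	0.5	0.67
6	BrPe0033	AT	8	60	5	237	249	0.72	0.3	0.65
7	BrPe0038	AT	6	60	5	154	176	0.73	0.6	0.64
8	BrPe0042	AT	8	60	6	142	160	0.71	0.8	0.63
9	BrPe0003	TC	11	55	5	277	291	0.7	0.4	0.62
10	BrPe0043	AT	8	60	4	199	207	0.71	0.5	0.6
11	BrPe0006	TC	10	55	4	193	199	0.68	0.4	0.59
12	BrPe0002	AG	12	55	3	177	185	0.69	0.56	0.58
13	BrPe0021	TA	7	55	3	158	164	0.67	0.25	0.56
14	BrPe0036	TC	6	60	4	197	203	0.65	0.1	0.54
15	BrPe0023	CT	7	55	6	118	132	0.57	0.4	0.52
16	BrPe3011	TTC	4	60	3	157	163	0.62	0.3	0.5
17	BrPe0037	TG	6	60	3	227	231	0.61	0.2	0.49
18	BrPe0010	TC	9	55	3	200	204	0.6	0.4	0.48
19	BrPe0001	CT	14	55	3	143	157	0.56	0.14	0.46
20	BrPe0012	AG	8	55	3	214	218	0.58	0.13	0.45
21	BrPe0008	AG	9	55	3	264	274	0.57	1	0.44
22	BrPe0025	GA	6	55	3	114	126	0.57	0.11	0.44
23	BrPe0039	AT	6	60	3	193	203	0.57	0.1	0.44
24	BrPe0050	TG	7	60	3	197	205	0.56	0.2	0.44
25	BrPe0013	AG	8	55	2	169	171	0.53	0	0.38
26	BrPe0020	GT	7	55	2	295	297	0.53	0	0.38
27	BrPe0034	CT	15	60	2	217	227	0.56	1	0.38
28	BrPe0049	TA	9	60	2	189	191	0.53	0.11	0.38
29	BrPe3012	TCT	4	60	2	181	183	0.53	0.11	0.38
30	BrPe0018	CT	7	55	3	135	149	0.43	0.3	0.37
31	BrPe0022	AG	7	55	2	98	104	0.51	0.2	0.37
32	BrPe0047	CT	9	60	2	186	192	0.48	0.3	0.35
33	BrPe3014	AGA	5	60	2	218	220	0.48	0.3	0.35
34	BrPe0007	AG	9	55	2	177	179	0.4	0.5	0.31
35	BrPe0027	TA	6	46	3	97	101	0.35	0.2	0.3
36	BrPe3027	GGT	4	60	3	178	202	0.35	0.4	0.3
37	BrPe0019	TC	7	55	2	210	214	0.36	0.14	0.28
38	BrPe0044	TA	6	60	2	217	219	0.33	0.38	0.26
39	BrPe0016	AG	7	55	2	277	279	0.21	0.22	0.18
40	BrPe0045	GT	8	60	2	183	185	0.21	0.22	0.18
41	BrPe0011	CT	8	53	2	74	80	0.19	0.2	0.16
42	BrPe0017	AG	7	55	2	86	90	0.19	0	0.16
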
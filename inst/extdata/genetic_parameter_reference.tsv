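year	trait	max	min	mean	SE	CV	CD5	CD1	sigma2_e	sigma2_g	sigma2_p	ECV	GCV	PCV	h2b	GA	GG
2019-20	PH	140.36	54.13	86.94	6.03	9.81	17.11	22.79	72.67	275.09	347.76	9.81	19.08	21.45	0.79	30.39	34.95
2019-20	NB	4.49	1.34	2.52	0.17	9.41	0.48	0.64	0.06	0.34	0.39	9.43	23.03	24.88	0.86	1.11	43.90
2019-20	NL	31.24	10.67	18.62	1.32	9.99	3.73	4.97	3.46	22.93	26.39	9.99	25.73	27.60	0.87	9.20	49.40
2019-20	NMR	2.75	0.92	1.61	0.11	9.66	0.31	0.42	0.02	0.20	0.22	9.66	27.52	29.17	0.89	0.86	53.48
2019-20	WMR	188.38	9.46	58.91	5.21	12.52	14.80	19.72	54.39	1094.78	1149.16	12.52	56.17	57.55	0.95	66.53	112.94
2019-20	NPF	10.76	1.94	5.67	0.41	10.15	1.15	1.54	0.33	3.58	3.92	10.15	33.42	34.93	0.92	3.73	65.87
2019-20	WPF	173.80	17.28	64.27	5.50	12.11	15.62	20.81	60.57	1188.63	1249.20	12.11	53.64	54.99	0.95	69.28	107.79
2019-20	NSF	16.78	2.91	8.38	0.61	10.28	1.73	2.30	0.74	9.67	10.42	10.28	37.13	38.52	0.93	6.18	73.71
2019-20	WSF	118.80	8.97	38.00	3.27	12.15	9.27	12.35	21.32	583.57	604.89	12.15	63.57	64.72	0.96	48.88	128.63
2019-20	LMR	10.07	3.49	6.04	0.42	9.74	1.18	1.57	0.35	1.30	1.65	9.74	18.91	21.27	0.79	2.09	34.62
2019-20	YPP	1603.80	47.53	242.51	27.40	15.98	77.75	103.60	1501.28	47066.27	48567.55	15.98	89.46	90.88	0.97	439.95	181.42
2019-20	FY	30.80	1.46	10.05	0.99	13.91	2.80	3.74	1.95	49.29	51.24	13.91	69.88	71.25	0.96	14.18	141.17
2020-21	PH	118.98	57.47	100.24	3.75	5.29	10.64	14.18	28.14	39.15	67.29	5.29	6.24	8.18	0.58	9.83	9.81
2020-21	NB	4.12	2.05	2.91	0.11	5.27	0.31	0.41	0.02	0.09	0.11	5.31	10.28	11.57	0.79	0.55	18.82
2020-21	NL	34.86	10.10	25.72	0.98	5.39	2.78	3.71	1.92	12.61	14.53	5.39	13.81	14.82	0.87	6.81	26.50
2020-21	NMR	3.09	0.95	1.51	0.06	5.66	0.17	0.23	0.01	0.22	0.22	5.65	30.73	31.25	0.97	0.94	62.26
2020-21	WMR	314.18	33.95	127.40	4.96	5.50	14.07	18.75	49.18	3592.61	3641.79	5.50	47.05	47.37	0.99	122.64	96.26
2020-21	NPF	9.19	0.97	2.15	0.10	6.74	0.29	0.39	0.02	1.07	1.09	6.71	48.23	48.70	0.98	2.11	98.42
2020-21	WPF	247.16	42.40	97.92	3.94	5.69	11.17	14.89	31.01	1751.90	1782.90	5.69	42.75	43.12	0.98	85.47	87.29
2020-21	NSF	22.31	5.83	11.69	0.46	5.61	1.32	1.76	0.43	9.36	9.80	5.62	26.17	26.77	0.96	6.16	52.71
2020-21	WSF	529.20	22.09	205.88	8.67	5.96	24.61	32.79	150.38	7732.94	7883.32	5.96	42.71	43.13	0.98	179.41	87.15
2020-21	LMR	12.76	5.06	8.98	0.33	5.27	0.95	1.26	0.22	1.47	1.69	5.27	13.50	14.49	0.87	2.33	25.90
2020-21	YPP	1161.83	146.60	488.05	20.04	5.81	56.88	75.79	803.48	36257.85	37061.33	5.81	39.02	39.45	0.98	387.98	79.50
2020-21	FY	36.55	4.19	20.96	0.81	5.47	2.30	3.06	1.31	57.99	59.31	5.46	36.34	36.75	0.98	15.51	74.03
2021-22	PH	139.53	77.19	106.16	5.40	7.19	15.31	20.40	58.23	136.59	194.82	7.19	11.01	13.15	0.70	20.16	18.99
2021-22	NB	11.56	2.47	5.62	0.30	7.65	0.86	1.15	0.18	2.48	2.67	7.65	28.01	29.04	0.93	3.13	55.67
2021-22	NL	39.16	13.02	24.83	1.29	7.36	3.66	4.88	3.33	24.08	27.41	7.35	19.77	21.09	0.88	9.48	38.16
2021-22	NMR	3.41	0.93	1.44	0.07	7.38	0.21	0.28	0.01	0.23	0.25	7.35	33.67	34.46	0.95	0.97	67.76
2021-22	WMR	315.00	23.04	77.47	4.39	8.01	12.45	16.59	38.51	1977.05	2015.56	8.01	57.40	57.95	0.98	90.72	117.10
2021-22	NPF	16.01	1.19	6.35	0.32	7.02	0.90	1.19	0.20	4.76	4.96	7.02	34.35	35.06	0.96	4.40	69.33
2021-22	WPF	319.99	40.61	112.88	6.50	8.15	18.45	24.59	84.55	2741.62	2826.17	8.15	46.39	47.10	0.97	106.24	94.12
2021-22	NSF	16.01	3.49	7.98	0.42	7.48	1.20	1.60	0.36	6.35	6.71	7.48	31.59	32.46	0.95	5.05	63.32
2021-22	WSF	384.30	27.89	87.81	5.39	8.68	15.29	20.37	58.07	3076.71	3134.78	8.68	63.17	63.76	0.98	113.20	128.92
2021-22	LMR	9.92	5.19	7.35	0.38	7.29	1.08	1.43	0.29	0.86	1.15	7.30	12.63	14.59	0.75	1.66	22.54
2021-22	YPP	721.09	97.27	281.32	15.71	7.90	44.57	59.39	493.43	15418.26	15911.70	7.90	44.14	44.84	0.97	251.79	89.51
2021-22	FY	47.70	3.80	19.54	1.09	7.89	3.09	4.12	2.38	90.37	92.74	7.89	48.65	49.29	0.97	19.33	98.93
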
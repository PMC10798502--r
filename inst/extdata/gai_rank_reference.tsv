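genotype	PH	NB	NL	NMR	WMR	NPF	WPF	NSF	WSF	LMR	YPP	FY	MR	R.MR	occurrence
BARI_Holud-1	40	48	41	5	47	29	20	33	3	45	24	21	29.67	34	2
BARI_Holud-2	43	47	31	32	39	36	42	28	26	25	47	39	36.25	44	0
BARI_Holud-3	28	35	34	9.5	21	43	27	29	28	43	33	24	29.54	33	1
BARI_Holud-4	11	23.5	25	22	13	20	11	12	13	7	20	14	15.96	10	1
BARI_Holud-5	16	21	14	26	42	40	35	34	43	47	38	25	31.75	38	0
T0008	24	43	38	43.5	12	18	13	13	15	19	21	35	24.54	22	0
T0012	41	46	43	15	34	13	12	6	27	41	27	37	28.50	30	1
T0013	48	29	35	36	45	25	30	10	32	23	40	48	33.42	40	1
T0015	17	6	20	43.5	19	33	28	30	33	11	29	8	23.13	18	2
T0016	39	44	24	8	40	31	34	7	2	48	15	29	26.75	26	3
T0017	20	33	8	53	37	28	37	11	17	4	42	31	26.75	27	2
T0019	47	3	16	25	22	1	22	8	42	44	19	11	21.67	16	3
T0023	30	53	23	47	33	51	41	15	8	8	9	30	29.00	36	3
T0052	49	51	44	18	46	52	49	53	52	51	50	51	47.17	51	0
T0061	13	15	29	22	5	17	8	41	38	17	14	9	19.00	15	3
T0063	23	7	22	49	25	30	31	40	41	16	36	32	29.33	32	0
T0066	27	23.5	32	41	17	24	15	27	20	46	11	13	24.71	23	1
T0077	52	40	51	3	48	37	25	50	25	53	31	49	38.67	45	1
T0082	7	2	10	9.5	2	32	7	1	11	2	3	5	7.63	3	10
T0083	32	10	9	30	38	41	48	35	44	39	43	40	34.08	42	2
T0084	14	17	19	6	31	7	16	22	19	21	28	12	17.67	11	2
T0085	18	13	11	19	8	9	10	17	16	14	5	10	12.50	7	5
T0093	35	9	2	52	32	5	18	26	40	1	12	27	21.58	15	4
T0094	6	12	5	2	14	3	29	32	24	31	22	3	15.25	9	5
T0095	36	30	18	22	50	12	47	20	31	42	44	42	32.83	39	0
T0095-1	31	25	42	40	35	46	39	48	45	40	32	43	38.83	46	0
T0096	12	27	53	48	16	38	40	46	30	6	39	16	30.92	37	1
T0097	8	34	26	14	11	16	23	18	21	26	16	22	19.58	14	1
T0098	21	28	30	33	29	6	21	31	35	35	30	34	27.75	29	1
T0102	19	4	39	31	28	19	32	25	23	29	34	15	24.83	24	1
T0103	3	1	1	27	23	11	1	37	22	10	8	2	12.17	6	7
T0104	45	41	36	42	43	48	45	44	50	13	41	50	41.50	48	0
T0105	33	38	28	16	20	26	33	23	9	18	17	33	24.50	21	1
T0106	5	5	3	7	6	14	19	16	5	27	2	6	9.58	4	8
T0107	26	19	12	36	26	2	24	4	48	20	49	26	24.33	20	2
T0108	51	42	50	38	41	8	4	47	18	22	18	19	29.83	36	2
T0109	42	49	48	50	51	53	53	52	51	50	53	53	50.42	53	0
T0116	22	8	6	29	27	42	44	38	34	33	23	20	27.17	28	2
T0117	1	11	17	4	4	10	6	14	10	3	10	1	7.58	2	9
T0118	10	18	15	46	36	47	14	36	14	38	26	17	26.42	25	1
T0119	9	20	27	11.5	18	35	26	24	36	15	35	18	22.88	17	1
T0121	4	26	7	1	1	4	2	5	1	30	1	7	7.42	1	10
T0122	50	31	37	51	53	49	50	45	46	52	37	46	45.58	49	0
T0123	15	50	40	20	7	23	46	39	39	24	25	28	29.67	35	1
T0124	29	36	47	45	24	21	38	42	37	5	46	44	34.50	43	1
T0126	44	37	33	34	9	44	5	2	4	28	13	36	24.08	19	4
T0127	53	45	52	36	52	39	52	51	53	49	52	52	48.83	52	0
T0128	34	32	46	28	30	27	36	19	29	34	45	45	33.75	41	0
T0129	2	22	13	17	15	22	9	21	7	36	7	4	14.58	8	5
T0130	46	52	49	24	49	50	51	49	49	37	51	47	46.17	50	0
T0132	25	16	4	13	3	15	3	3	6	12	4	23	10.58	5	6
T0133	37	39	45	39	44	34	43	43	47	32	48	38	40.75	47	0
T0134	38	14	21	11.5	10	45	17	9	12	9	6	41	19.46	13	4
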
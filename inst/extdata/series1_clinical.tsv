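id	age	sex	karnofsky	location	hemisphere	os_months	event	surgery	chemotherapy
GBM1	80	M	NA	Temporal	L	6	1	T	ND
GBM2	75	M	80	Fronto-temporal	R	22	1	T	Stupp
GBM3	61	F	90	Parietal	R	83	1	T	Stupp
GBM4	73	M	100	Temporal	L	19	1	P	Stupp
GBM5	38	M	90	Frontal	R	15	1	T	Stupp
GBM6	49	F	60	Frontal	R	30	0	P	Stupp
GBM7	41	M	40	Temporal	R	11	1	P	Stupp
GBM8	57	M	90	Tempo-parietal	R	6	1	T	Stupp
GBM9	72	M	90	Temporal	R	28	0	P	Stupp
GBM10	62	M	100	Parietal	R	28	0	T	Stupp
GBM11	71	M	80	Temporal	R	27	1	P	Stupp
GBM12	50	F	100	Temporal	R	13	1	T	Stupp
GBM13	72	F	70	Temporal	R	9	1	P	Stupp
GBM14	78	F	100	Frontal	R	6	1	T	-
GBM15	61	F	100	Frontal	R	25	0	T	Stupp
GBM16	54	M	100	Fronto-parietal	R	2	1	T	Stupp
GBM17	52	M	80	Frontal	R	63	1	P	Stupp
GBM18	57	F	90	Temporal	R	10	1	P	Stupp
GBM19	68	M	90	Occipital	L	10	1	T	Stupp
GBM20	82	F	80	Frontal	L	7	1	T	-
GBM21	77	M	70	Temporal	R	6	1	P	-
GBM22	69	F	100	Frontal	L	8	1	T	Stupp
GBM23	24	F	80	Frontal	L	21	1	P	Stupp
G97	53	M	80	Temporal	R	21	1	T	Stupp
G94	79	F	80	Temporal	R	9	1	P	-
G93	63	M	80	Occipital	R	29	1	T	Stupp
G92	54	F	80	Parietal	R	15	1	T	Stupp
G91	73	F	60	Occipital	R	13	1	P	Stupp
G90	57	F	60	Parietal	L	5	1	B	-
G89	51	M	80	Temporal	R	2	1	P	-
G88	71	M	80	Parietal	R	8	1	P	Stupp
G87	45	M	80	Temporal	L	16	1	P	Stupp/Sequential
G83	75	M	70	Temporal	R	10	1	P	-
G82	78	M	70	Frontal	R	2	1	B	-
G81	62	F	70	Frontal	R	13	1	P	Stupp
G80	43	M	80	Frontal	R	18	1	T	Stupp
G79	71	F	60	Occipital	R	6	1	B	-
G73	78	F	60	Parietal	L	4	1	B	-
G72	77	F	70	Temporal	L	1	1	P	-
G71	66	F	60	Parietal	R	10	1	P	Sequential
G70	56	F	80	Occipital	L	21	1	P	Stupp
G68	72	M	70	Insular	L	26	1	T	Stupp
G67	68	F	80	Parietal	R	35	1	P	Stupp
G66	60	M	80	Occipital	R	14	1	T	Stupp
G65	69	F	60	Parietal	L	1	1	P	-
G64	57	M	60	Occipital	L	8	1	P	Sequential
G63	61	F	60	Insular	R	13	1	P	Sequential
G62	57	F	90	Occipital	R	18	1	T	Stupp
G57	34	M	90	Frontal	R	8	1	T	Stupp
G56	65	M	80	Frontal	L	13	1	P	Stupp
G55	54	F	80	Frontal	R	17	1	P	Stupp
G54	65	F	60	Parietal	L	6	1	P	-
G53	74	M	60	Frontal	L	29	1	T	Stupp
G52	56	M	90	Frontal	L	21	1	B	Stupp
G51	60	M	60	Temporal	R	2	1	B	-
G50	84	M	70	Temporal	R	11	1	P	-
G46	62	M	60	Frontal	L	3	1	P	-
G45	76	F	60	Temporal	R	10	1	P	-
G44	48	M	80	Frontal	L	22	1	P	PCV
G43	67	F	70	Temporal	R	7	1	P	-
G42	67	M	80	Temporal	R	2	1	P	-
G41	44	F	60	Frontal	R	14	1	B	Sequential
G40	45	F	80	Frontal	R	15	1	P	BCNU+TMZ
G39	70	F	50	Frontal	R	18	1	P	Stupp
G37	70	M	80	Temporal	R	32	1	T	Stupp
G35	50	F	80	Frontal	L	2	1	P	-
G34	69	M	60	Temporal	R	5	1	B	-
G31	71	F	90	Frontal	R	7	1	P	-
G30	71	F	70	Temporal	R	9	1	B	-
G29	49	F	80	Parietal	L	12	1	B	Sequential
G25	68	M	80	Frontal	L	6	1	P	Stupp
G23	50	F	70	Frontal	R	14	1	B	Stupp
G17	30	F	90	Temporal	R	67	1	P	Sequential
G15	79	M	80	Parietal	L	5	1	T	Sequential
G14	69	F	70	Frontal	R	0	1	B	-
G13	39	F	90	Frontal	R	20	1	P	Sequential
G12	74	M	70	Temporal	R	1	1	B	-
G10	35	F	80	Temporal	L	15	1	P	Stupp
G8	67	F	90	Deep	NA	9	1	P	Stupp
G6	70	F	80	Temporal	R	19	1	P	Stupp
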
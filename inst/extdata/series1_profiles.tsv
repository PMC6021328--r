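tumor_id	arms	bands	egfr_involved
G94	7p	7p11.2,7p12.1	1
G55	7p	7p11.2	1
G91	7p	7p11.2	1
G80	7p	7p11.2	1
G72	7p	7p11.2	1
G68	7p	7p11.2	1
G67	7p	7p11.2	1
G56	7p	7p11.2	1
G44	7p	7p11.2	1
G40	7p	7p11.2	1
G37	7p	7p11.2	1
G30	7p	7p11.2	1
GBM3	7p	7p11.2	1
GBM7	7p	7p11.2	1
GBM11	7p	7p11.2	1
GBM12	7p	7p11.2	1
GBM17	7p	7p11.2	1
G73	4q	4q11,4q12,4q13.3	0
G12	4q	4q11,4q12	0
GBM1	4q	4q12	0
GBM14	4q	4q12	0
G51	12q	12q13.3,12q14.1	0
G46	12q	12q14.1,12q14.2,12q14.3,12q15	0
G25	12q	12q14.1	0
G79	1q	1q32.1	0
G54	1q	1q32.1	0
G10	16q	16q12.1,16q12.2	0
G39	7p,12q	7p11.2,12q13.3,12q14.1	1
G41	7p,12q	7p11.2,12q14.1,12q15	1
G53	7p,7q	7p21.1,7p12.3,7p11.2,7q22.3	1
G70	7p,12q	7p11.2,7p21.3,7p22.1,12q15	1
G83	7p,12q	7p11.2,12q13.3,12q14.1	1
G65	1q,7p	1q32.1,7p11.2	1
GBM19	1q,7p	1q32.1,7p11.2	1
G23	1q,7p,12q	1q32.1,7p11.2,12q13.3,12q14.1	1
GBM4	7p,11p	7p11.2,11p13	1
G82	4q,7p,12q	4q12,4q13.3,7p11.2,12q13.12,12q13.13,12q13.3,12q14.1,12q15	1
G90	5q,6q,7p	5q34,6q25,7p11.2	1
G81	7p,17p,17q	7p11.2,17p13.1,17q25.1	1
G71	7p,11p,11q,12q	7p11.2,7p12.1,11p15.3,11p11.2,11q13.3,11q25,12q13.3,12q14.1	1
GBM13	4q,12q	4q12,12q14.1	0
GBM22	4q,12q	4q12,12q13.3,12q14.1	0
G8	1p,7q	1p12,1p13,1p21,7q21.2,7q21.3	0
G88	4q,7q,12q	4q12,4q13.3,7q31.2,12q13.3,12q14.1,12q15,12q21.1	0
G89	1p,12q,17q	1p36.21,12q13.3,12q14.1,17q11.2,17q12,17q21,17q22,17q24	0
GBM2			0
GBM5			0
GBM6			0
GBM8			0
GBM9			0
GBM10			0
GBM15			0
GBM16			0
GBM18			0
GBM20			0
GBM21			0
GBM23			0
G97			0
G93			0
G92			0
G87			0
G66			0
G64			0
G63			0
G62			0
G57			0
G52			0
G50			0
G45			0
G43			0
G42			0
G35			0
G34			0
G31			0
G29			0
G17			0
G15			0
G14			0
G13			0
G6			0
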
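chr1	0	12700000	pf1	gneg
chr1	12700000	16200000	p36.21	gpos50
chr1	16200000	55250000	pf2	gneg
chr1	55250000	94300000	pf3	gpos50
chr1	94300000	106700000	p21	gneg
chr1	106700000	107200000	pf4	gpos50
chr1	107200000	116100000	p13	gneg
chr1	116100000	120600000	p12	gpos50
chr1	120600000	121500000	pf5	gneg
chr1	121500000	1.25e+08	p11.1	acen
chr1	1.25e+08	128900000	q11.1	acen
chr1	128900000	163800000	qf1	gpos50
chr1	163800000	198700000	qf2	gneg
chr1	198700000	205300000	q32.1	gpos50
chr1	205300000	227275310	qf3	gneg
chr1	227275310	249250621	qf4	gpos50
chr2	0	30333333	pf1	gneg
chr2	30333333	60666667	pf2	gpos50
chr2	60666667	9.1e+07	pf3	gneg
chr2	9.1e+07	93300000	p11.1	acen
chr2	93300000	95300000	q11.1	acen
chr2	95300000	132274843	qf1	gpos50
chr2	132274843	169249686	qf2	gneg
chr2	169249686	206224530	qf3	gpos50
chr2	206224530	243199373	qf4	gneg
chr3	0	29833333	pf1	gneg
chr3	29833333	59666667	pf2	gpos50
chr3	59666667	89500000	pf3	gneg
chr3	89500000	9.1e+07	p11.1	acen
chr3	9.1e+07	93500000	q11.1	acen
chr3	93500000	128340810	qf1	gpos50
chr3	128340810	163181620	qf2	gneg
chr3	163181620	198022430	qf3	gpos50
chr4	0	24100000	pf1	gneg
chr4	24100000	48200000	pf2	gpos50
chr4	48200000	50400000	p11.1	acen
chr4	50400000	52700000	q11.1	acen
chr4	52700000	59500000	q12	gneg
chr4	59500000	68600000	qf1	gpos50
chr4	68600000	75300000	q13.3	gneg
chr4	75300000	113918092	qf2	gpos50
chr4	113918092	152536184	qf3	gneg
chr4	152536184	191154276	qf4	gpos50
chr5	0	23050000	pf1	gneg
chr5	23050000	46100000	pf2	gpos50
chr5	46100000	48400000	p11.1	acen
chr5	48400000	50700000	q11.1	acen
chr5	50700000	87300000	qf1	gneg
chr5	87300000	123900000	qf2	gpos50
chr5	123900000	160500000	qf3	gneg
chr5	160500000	168900000	q34	gpos50
chr5	168900000	180915260	qf4	gneg
chr6	0	29350000	pf1	gneg
chr6	29350000	58700000	pf2	gpos50
chr6	58700000	6.1e+07	p11.1	acen
chr6	6.1e+07	63300000	q11.1	acen
chr6	63300000	91866667	qf1	gneg
chr6	91866667	120433333	qf2	gpos50
chr6	120433333	1.49e+08	qf3	gneg
chr6	1.49e+08	1.61e+08	q25	gpos50
chr6	1.61e+08	171115067	qf4	gneg
chr7	0	4500000	pf1	gneg
chr7	4500000	7300000	p22.1	gpos50
chr7	7300000	13800000	p21.3	gneg
chr7	13800000	16500000	p21.2	gpos50
chr7	16500000	20900000	p21.1	gneg
chr7	20900000	45400000	pf2	gpos50
chr7	45400000	4.9e+07	p12.3	gneg
chr7	4.9e+07	50500000	p12.2	gpos50
chr7	50500000	53900000	p12.1	gneg
chr7	53900000	5.8e+07	p11.2	gpos50
chr7	5.8e+07	59900000	p11.1	acen
chr7	59900000	61700000	q11.1	acen
chr7	61700000	91100000	qf1	gneg
chr7	91100000	92800000	q21.2	gpos50
chr7	92800000	9.8e+07	q21.3	gneg
chr7	9.8e+07	104500000	qf2	gpos50
chr7	104500000	107400000	q22.3	gneg
chr7	107400000	114600000	qf3	gpos50
chr7	114600000	117400000	q31.2	gneg
chr7	117400000	138269332	qf4	gpos50
chr7	138269332	159138663	qf5	gneg
chr8	0	21550000	pf1	gneg
chr8	21550000	43100000	pf2	gpos50
chr8	43100000	45600000	p11.1	acen
chr8	45600000	48100000	q11.1	acen
chr8	48100000	80854674	qf1	gneg
chr8	80854674	113609348	qf2	gpos50
chr8	113609348	146364022	qf3	gneg
chr9	0	23650000	pf1	gneg
chr9	23650000	47300000	pf2	gpos50
chr9	47300000	4.9e+07	p11.1	acen
chr9	4.9e+07	50700000	q11.1	acen
chr9	50700000	80871144	qf1	gneg
chr9	80871144	111042287	qf2	gpos50
chr9	111042287	141213431	qf3	gneg
chr10	0	3.8e+07	pf1	gneg
chr10	3.8e+07	40200000	p11.1	acen
chr10	40200000	42300000	q11.1	acen
chr10	42300000	73378249	qf1	gpos50
chr10	73378249	104456498	qf2	gneg
chr10	104456498	135534747	qf3	gpos50
chr11	0	10700000	pf1	gneg
chr11	10700000	12700000	p15.3	gpos50
chr11	12700000	3.1e+07	pf2	gneg
chr11	3.1e+07	36400000	p13	gpos50
chr11	36400000	43500000	pf3	gneg
chr11	43500000	48800000	p11.2	gpos50
chr11	48800000	51600000	pf4	gneg
chr11	51600000	53700000	p11.1	acen
chr11	53700000	55700000	q11.1	acen
chr11	55700000	68700000	qf1	gpos50
chr11	68700000	70500000	q13.3	gneg
chr11	70500000	100400000	qf2	gpos50
chr11	100400000	130300000	qf3	gneg
chr11	130300000	135006516	q25	gpos50
chr12	0	33300000	pf1	gneg
chr12	33300000	35800000	p11.1	acen
chr12	35800000	38200000	q11.1	acen
chr12	38200000	49200000	qf1	gpos50
chr12	49200000	51700000	q13.12	gneg
chr12	51700000	54400000	q13.13	gpos50
chr12	54400000	56200000	q13.2	gneg
chr12	56200000	58100000	q13.3	gpos50
chr12	58100000	62700000	q14.1	gneg
chr12	62700000	64400000	q14.2	gpos50
chr12	64400000	67500000	q14.3	gneg
chr12	67500000	71500000	q15	gpos50
chr12	71500000	75700000	q21.1	gneg
chr12	75700000	104775948	qf2	gpos50
chr12	104775948	133851895	qf3	gneg
chr13	0	16300000	pf1	gneg
chr13	16300000	17900000	p11.1	acen
chr13	17900000	19500000	q11.1	acen
chr13	19500000	51389959	qf1	gpos50
chr13	51389959	83279919	qf2	gneg
chr13	83279919	115169878	qf3	gpos50
chr14	0	16100000	pf1	gneg
chr14	16100000	17600000	p11.1	acen
chr14	17600000	19100000	q11.1	acen
chr14	19100000	48516513	qf1	gpos50
chr14	48516513	77933027	qf2	gneg
chr14	77933027	107349540	qf3	gpos50
chr15	0	15800000	pf1	gneg
chr15	15800000	1.9e+07	p11.1	acen
chr15	1.9e+07	20700000	q11.1	acen
chr15	20700000	47977131	qf1	gpos50
chr15	47977131	75254261	qf2	gneg
chr15	75254261	102531392	qf3	gpos50
chr16	0	35300000	pf1	gneg
chr16	35300000	36600000	p11.1	acen
chr16	36600000	38300000	q11.1	acen
chr16	38300000	46400000	qf1	gpos50
chr16	46400000	52600000	q12.1	gneg
chr16	52600000	56700000	q12.2	gpos50
chr16	56700000	90354753	qf2	gneg
chr17	0	6500000	pf1	gneg
chr17	6500000	10700000	p13.1	gpos50
chr17	10700000	22200000	pf2	gneg
chr17	22200000	2.4e+07	p11.1	acen
chr17	2.4e+07	25800000	q11.1	acen
chr17	25800000	31800000	q11.2	gpos50
chr17	31800000	38100000	q12	gneg
chr17	38100000	50200000	q21	gpos50
chr17	50200000	57600000	q22	gneg
chr17	57600000	62600000	q23	gpos50
chr17	62600000	67400000	q24	gneg
chr17	67400000	70900000	qf1	gpos50
chr17	70900000	74800000	q25.1	gneg
chr17	74800000	81195210	qf2	gpos50
chr18	0	15400000	pf1	gneg
chr18	15400000	17200000	p11.1	acen
chr18	17200000	1.9e+07	q11.1	acen
chr18	1.9e+07	48538624	qf1	gpos50
chr18	48538624	78077248	qf2	gneg
chr19	0	24400000	pf1	gneg
chr19	24400000	26500000	p11.1	acen
chr19	26500000	28600000	q11.1	acen
chr19	28600000	59128983	qf1	gpos50
chr20	0	25600000	pf1	gneg
chr20	25600000	27500000	p11.1	acen
chr20	27500000	29400000	q11.1	acen
chr20	29400000	63025520	qf1	gpos50
chr21	0	10900000	pf1	gneg
chr21	10900000	13200000	p11.1	acen
chr21	13200000	14300000	q11.1	acen
chr21	14300000	48129895	qf1	gpos50
chr22	0	12200000	pf1	gneg
chr22	12200000	14700000	p11.1	acen
chr22	14700000	17900000	q11.1	acen
chr22	17900000	51304566	qf1	gpos50
chrX	0	29050000	pf1	gneg
chrX	29050000	58100000	pf2	gpos50
chrX	58100000	60600000	p11.1	acen
chrX	60600000	6.3e+07	q11.1	acen
chrX	6.3e+07	93756853	qf1	gneg
chrX	93756853	124513707	qf2	gpos50
chrX	124513707	155270560	qf3	gneg
chrY	0	11600000	pf1	gneg
chrY	11600000	12500000	p11.1	acen
chrY	12500000	13400000	q11.1	acen
chrY	13400000	36386783	qf1	gpos50
chrY	36386783	59373566	qf2	gneg
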
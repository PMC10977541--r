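# Condensed cytogenetic band table for GRCh37/hg19 (synthetic fixture).
# Authored from standard hg19 ideogram coordinates; condensed to major
# bands except on chr7/13/15/18/21/X/Y, where sub-band resolution is
# retained for the regions the packaged reports reference. Coordinates
# are 1-based inclusive and tile each chromosome exactly. The chr21
# q11.1/q11.2 boundary is drawn so that position 14,300,000 lies in
# q11.2 (the dominant reporting convention for the trisomy-21 region).
# Columns: chrom  start  end  band  stain
chr1	1	2300000	p36.33	gneg
chr1	2300001	120000000	p31	gpos50
chr1	120000001	125000000	p11.1	acen
chr1	125000001	128000000	q11	acen
chr1	128000001	246000000	q21	gpos50
chr1	246000001	249250621	q44	gneg
chr2	1	4400000	p25.3	gneg
chr2	4400001	88000000	p16	gpos50
chr2	88000001	93300000	p11.1	acen
chr2	93300001	96800000	q11.1	acen
chr2	96800001	239000000	q22	gpos50
chr2	239000001	243199373	q37.3	gneg
chr3	1	2800000	p26.3	gneg
chr3	2800001	87000000	p14	gpos50
chr3	87000001	91000000	p11.1	acen
chr3	91000001	93500000	q11.1	acen
chr3	93500001	194000000	q21	gpos50
chr3	194000001	198022430	q29	gneg
chr4	1	4500000	p16.3	gneg
chr4	4500001	48200000	p15	gpos50
chr4	48200001	50400000	p11	acen
chr4	50400001	52700000	q11	acen
chr4	52700001	187000000	q21	gpos50
chr4	187000001	191154276	q35.2	gneg
chr5	1	4500000	p15.33	gneg
chr5	4500001	46100000	p14	gpos50
chr5	46100001	48400000	p11	acen
chr5	48400001	50700000	q11.1	acen
chr5	50700001	176500000	q21	gpos50
chr5	176500001	180915260	q35.3	gneg
chr6	1	2300000	p25.3	gneg
chr6	2300001	58700000	p21	gpos50
chr6	58700001	61000000	p11.1	acen
chr6	61000001	63300000	q11.1	acen
chr6	63300001	167000000	q21	gpos50
chr6	167000001	171115067	q27	gneg
chr7	1	2800000	p22.3	gneg
chr7	2800001	45000000	p21	gpos50
chr7	45000001	60000000	p11.1	acen
chr7	60000001	62000000	q11.1	acen
chr7	62000001	155000000	q21	gpos50
chr7	155000001	159138663	q36.3	gneg
chr8	1	2200000	p23.3	gneg
chr8	2200001	43100000	p12	gpos50
chr8	43100001	45600000	p11.1	acen
chr8	45600001	47800000	q11.1	acen
chr8	47800001	142000000	q21	gpos50
chr8	142000001	146364022	q24.3	gneg
chr9	1	2200000	p24.3	gneg
chr9	2200001	47300000	p13	gpos50
chr9	47300001	49000000	p11.1	acen
chr9	49000001	50700000	q11	acen
chr9	50700001	137400000	q21	gpos50
chr9	137400001	141213431	q34.3	gneg
chr10	1	3000000	p15.3	gneg
chr10	3000001	38000000	p12	gpos50
chr10	38000001	40200000	p11.1	acen
chr10	40200001	42300000	q11.1	acen
chr10	42300001	130600000	q21	gpos50
chr10	130600001	135534747	q26.3	gneg
chr11	1	2800000	p15.5	gneg
chr11	2800001	51600000	p13	gpos50
chr11	51600001	53700000	p11.11	acen
chr11	53700001	55700000	q11	acen
chr11	55700001	130800000	q21	gpos50
chr11	130800001	135006516	q25	gneg
chr12	1	3300000	p13.33	gneg
chr12	3300001	33300000	p12	gpos50
chr12	33300001	35800000	p11.1	acen
chr12	35800001	38200000	q11	acen
chr12	38200001	129300000	q21	gpos50
chr12	129300001	133851895	q24.33	gneg
chr13	1	4500000	p13	gvar
chr13	4500001	16300000	p11.2	gvar
chr13	16300001	17900000	p11.1	acen
chr13	17900001	19499999	q11	acen
chr13	19500000	23300000	q12.11	gneg
chr13	23300001	110300000	q21	gpos50
chr13	110300001	115169878	q34	gneg
chr14	1	3700000	p13	gvar
chr14	3700001	16100000	p11.2	gvar
chr14	16100001	17600000	p11.1	acen
chr14	17600001	19100000	q11.1	acen
chr14	19100001	104000000	q21	gpos50
chr14	104000001	107349540	q32.33	gneg
chr15	1	3900000	p13	gvar
chr15	3900001	17000000	p11.2	gvar
chr15	17000001	19000000	p11.1	acen
chr15	19000001	20700000	q11.1	acen
chr15	20700001	25500000	q11.2	gneg
chr15	25500001	98500000	q21	gpos50
chr15	98500001	102531392	q26.3	gneg
chr16	1	7900000	p13.3	gneg
chr16	7900001	34600000	p12	gpos50
chr16	34600001	36600000	p11.1	acen
chr16	36600001	38600000	q11.1	acen
chr16	38600001	87100000	q21	gpos50
chr16	87100001	90354753	q24.3	gneg
chr17	1	3300000	p13.3	gneg
chr17	3300001	22200000	p12	gpos50
chr17	22200001	24000000	p11.1	acen
chr17	24000001	25800000	q11.1	acen
chr17	25800001	77800000	q21	gpos50
chr17	77800001	81195210	q25.3	gneg
chr18	1	2900000	p11.32	gneg
chr18	2900001	7100000	p11.31	gpos50
chr18	7100001	15400000	p11.21	gneg
chr18	15400001	17200000	p11.1	acen
chr18	17200001	19000000	q11.1	acen
chr18	19000001	43500000	q12	gpos50
chr18	43500001	66500000	q21	gneg
chr18	66500001	73100000	q22	gpos50
chr18	73100001	78077248	q23	gneg
chr19	1	6900000	p13.3	gneg
chr19	6900001	24400000	p12	gpos50
chr19	24400001	26500000	p11	acen
chr19	26500001	28600000	q11	acen
chr19	28600001	56300000	q13.1	gpos50
chr19	56300001	59128983	q13.43	gneg
chr20	1	5100000	p13	gneg
chr20	5100001	25600000	p12	gpos50
chr20	25600001	27500000	p11.1	acen
chr20	27500001	29400000	q11.1	acen
chr20	29400001	60100000	q13.1	gpos50
chr20	60100001	63025520	q13.33	gneg
chr21	1	2800000	p13	gvar
chr21	2800001	6800000	p12	gvar
chr21	6800001	13200000	p11	acen
chr21	13200001	14299999	q11.1	acen
chr21	14300000	16400000	q11.2	gneg
chr21	16400001	31500000	q21	gpos50
chr21	31500001	42600000	q22.1	gneg
chr21	42600001	48129895	q22.3	gneg
chr22	1	3800000	p13	gvar
chr22	3800001	13700000	p11.2	gvar
chr22	13700001	14700000	p11.1	acen
chr22	14700001	15500000	q11.1	acen
chr22	15500001	48100000	q13.1	gpos50
chr22	48100001	51304566	q13.33	gneg
chrX	1	4300000	p22.33	gneg
chrX	4300001	6000000	p22.32	gpos50
chrX	6000001	9500000	p22.31	gneg
chrX	9500001	37600000	p21	gpos50
chrX	37600001	60600000	p11	gneg
chrX	60600001	63000000	q11	acen
chrX	63000001	92000000	q21	gpos50
chrX	92000001	118300000	q24	gneg
chrX	118300001	147100000	q26	gpos50
chrX	147100001	155270560	q28	gneg
chrY	1	2650000	p11.32	gneg
chrY	2650001	10400000	p11.2	gpos50
chrY	10400001	12500000	p11.1	acen
chrY	12500001	13400000	q11.1	acen
chrY	13400001	28800000	q11.2	gneg
chrY	28800001	59373566	q12	gvar
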
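# published per-library statistics for 29 black pepper ddRAD GBS genotypes
genotype	pe_reads	gc_pct	scaffolds	ssrs
2070	2910820	40	814442	6758
4216	2453308	40	733176	5751
4226	3560292	39	587874	6153
5641	1419137	40.5	266974	2033
816	1271425	40	267918	2229
CE	293718	40	136099	1118
CHERI	1652135	40	305448	2282
P1	2219162	39.5	316786	2408
P2	213631	41	82713	1007
P3	861024	39	378171	3384
P4	935613	40	229541	1747
P5	1162094	39	290715	2447
P6	1959805	39	489107	3794
P7	1876837	39.5	466331	3650
P8	1133968	39	434763	4151
GIRI	2818577	40	716463	5910
ME	539793	39	240190	2227
KS	1776541	39.5	924676	9309
OP-P24	2218687	40.5	327345	2501
PAN	1550235	39	572412	5063
PLD	2498978	39	361046	3098
P.ATT	3539707	39.5	771154	8551
POU	1341198	40	273567	2146
SHAK	2238734	40	669590	5888
SRE	2293560	40.5	393255	2956
SUB	1831430	40	457158	3580
VAD	2174345	40.5	621325	4788
THE	3059600	39	685171	5902
UTHI	1616470	40.5	319043	2491
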
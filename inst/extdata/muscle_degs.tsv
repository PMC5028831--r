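gene	mean_qhmm	mean_sth	log2fc	fdr	style	bp_terms
BCL9L	364.4	156.2	-1.2	5.16e-03	down	7
BTG1	670.5	3228.5	2.3	9.08e-05	up	4,10
CASQ1	45168.0	17353.3	-1.4	5.41e-04	down	1,8
CASQ2	620.4	248.1	-1.3	1.90e-02	down	8
CDH15	122.5	263.7	1.1	1.66e-03	up	5
CITED2	155.9	289.7	0.9	2.54e-02	up	7
CSRP3	4896.3	18425.4	2.0	4.61e-02	up	1,9
FHOD3	502.7	172.0	-1.5	0	down	8,9
FOXP1	233.3	382.1	0.7	2.45e-02	up	1,8
GPX1	1529.1	761.9	-1.0	1.22e-06	down	3
HEYL	310.0	186.4	-0.7	7.27e-05	down	7
HLF	76.3	31.7	-1.3	1.02e-04	down	7
ITGA7	4307.8	1157.3	-1.9	0	down	1
KIAA1161	661.6	214.7	-1.6	1.19e-06	down	3
LMOD2	5623.4	12507.3	1.2	1.18e-08	up	9
MAFF	73.1	239.3	1.7	1.89e-03	up	7
MYF6	1688.6	4474.1	1.4	0	up	1,2,4,6,7,8,10
MYH6	12787.7	4502.7	-1.5	1.17e-10	down	8,9
MYL2	63933.5	23309.3	-1.5	7.13e-12	down	9
MYL6B	12018.3	1654.6	-2.9	3.77e-02	down	1
MYLK3	265.8	94.1	-1.5	6.03e-06	down	8,9
MYOD1	232.5	37.5	-2.6	3.46e-06	down	1,2,3,4,6,7,8,10
MYOG	501.8	148.6	-1.8	2.41e-04	down	1,2,3,4,6,7,8,10
NEO1	390.1	178.1	-1.1	2.90e-06	down	5
OMYHCS	225230.0	88659.7	-1.3	3.66e-14	down	8,9
PPP3CB	1978.0	1122.0	-0.8	3.85e-02	down	3
RXRG	1104.1	273.7	-2.0	2.89e-06	down	1
SETD3	1297.1	719.0	-0.9	1.02e-04	down	5
STAC3	5060.1	2569.4	-1.0	4.65e-03	down	3
XIRP1	7518.7	37631.7	2.3	1.11e-06	up	8
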
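2	175830952	175831951	CHN1	0	+	175830952	175831951	0	2	200,200,	0,799,
17	57732582	57745581	CLTC	0	+	57732582	57745581	0	14	200,200,200,200,200,200,200,200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,6000,7000,8000,9000,10000,11000,12000,12799,
11	108573973	108584157	DDX10	0	+	108573973	108584157	0	11	200,200,200,200,200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,6000,7000,8000,9000,9984,
21	41867800	41870799	DSCAM	0	+	41867800	41870799	0	4	200,200,200,200,	0,1000,2000,2799,
4	66408862	66412143	EPHA5	0	+	66408862	66412143	0	4	200,200,200,200,	0,1000,2000,3081,
8	72207670	72218477	EYA1	0	+	72207670	72218477	0	8	200,200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,6000,10607,
11	106612704	106623667	GUCY1A2	0	+	106612704	106623667	0	8	200,200,200,200,200,200,3963,200,	0,1000,2000,3000,4000,5000,6000,10763,
5	134714422	134721308	H2AFY	0	+	134714422	134721308	0	3	200,200,200,	0,1000,6686,
10	65203515	65204514	JMJD1C	0	+	65203515	65204514	0	2	200,200,	0,799,
5	137727530	137745076	KDM3B	0	+	137727530	137745076	0	12	200,200,200,200,200,200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,6000,7000,8000,9000,10000,17346,
10	24434905	24439256	KIAA1217	0	+	24434905	24439256	0	3	200,200,200,	0,1000,4151,
17	25902301	25905300	KSR1	0	+	25902301	25905300	0	4	200,200,200,200,	0,1000,2000,2799,
X	153147899	153152898	LCA10	0	+	153147899	153152898	0	6	200,200,200,200,200,200,	0,1000,2000,3000,4000,4799,
4	151251080	151299079	LRBA	0	+	151251080	151299079	0	49	200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,6000,7000,8000,9000,10000,11000,12000,13000,14000,15000,16000,17000,18000,19000,20000,21000,22000,23000,24000,25000,26000,27000,28000,29000,30000,31000,32000,33000,34000,35000,36000,37000,38000,39000,40000,41000,42000,43000,44000,45000,46000,47000,47799,
3	168892255	168894254	MECOM	0	+	168892255	168894254	0	3	200,200,200,	0,1000,1799,
2	172893409	172894408	METAP1D	0	+	172893409	172894408	0	2	200,200,	0,799,
21	47148499	47149498	PCBP3	0	+	47148499	47149498	0	2	200,200,	0,799,
2	120326408	120335556	PCDP1	0	+	120326408	120335556	0	7	200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,8948,
12	48514677	48517676	PFKM	0	+	48514677	48517676	0	4	200,200,200,200,	0,1000,2000,2799,
10	22887425	22892865	PIP4K2A	0	+	22887425	22892865	0	4	200,200,200,200,	0,1000,2000,5240,
21	35916566	35917565	RCAN1	0	+	35916566	35917565	0	2	200,200,	0,799,
15	60699999	61400199	RORA	0	-	60699999	61400199	0	3	200,200,200,	0,3e+05,7e+05,
13	21735882	21745467	SKA3	0	-	21735882	21745467	0	5	201,201,200,200,200,	0,6385,7385,8385,9385,
3	47805474	47807473	SMARCC1	0	+	47805474	47807473	0	3	200,200,200,	0,1000,1799,
2	65561571	65563570	SPRED2	0	+	65561571	65563570	0	3	200,200,200,	0,1000,1799,
15	71745138	71751137	THSD4	0	+	71745138	71751137	0	7	200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,5799,
17	38988773	38991974	TMEM99	0	+	38988773	38991974	0	4	200,200,201,200,	0,1000,2000,3001,
3	170852987	170864986	TNIK	0	+	170852987	170864986	0	13	200,200,200,200,200,200,200,200,200,200,200,200,200,	0,1000,2000,3000,4000,5000,6000,7000,8000,9000,10000,11000,11799,
19	30943607	30951549	ZNF536	0	+	30943607	30951549	0	3	200,200,200,	0,1000,7742,
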
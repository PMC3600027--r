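sample_id	type	chrom1	breakpoint1	chrom2	breakpoint2	disrupted_genes
153T	deletion	11	106618805	11	106622567	GUCY1A2 (exon 7)
154T	deletion	8	72214170	8	72217978	EYA1 (intron 7-8)
119T	deletion	5	134715922	5	134720809	H2AFY (intron 2-3)
149T	deletion	2	12526265	2	12528008
149T	deletion	2	65366656	2	65369602
149T	deletion	10	22889925	10	22892366	PIP4K2A (intron 3-4)
149T	deletion	15	45915722	15	45917969
152T	deletion	12	2130488	12	2133385
120T	inversion	2	120331908	2	120335057	PCDP1 (intron 6-7)
116T	inversion	5	129549038	5	129552347
149T	inversion	10	24436405	10	24438757	KIAA1217 (intron 2-3)
153T	inversion	2	172893909	2	175831452	METAP1D (intron 1-2); CHN1 (intron 1-2)
116T	inversion	3	168893755	3	170864487	MECOM (intron 2-3); TNIK (intron 12-13)
151T	inversion	5	137738030	5	137744577	KDM3B (intron 11-12)
153T	translocation	2	42052398	4	66411362	EPHA5 (intron 3-4)
153T	translocation	6	104501617	X	152223450
153T	translocation	7	54909974	19	29832131
153T	translocation	8	57916723	19	30951050	ZNF536 (intron 2-3)
153T	translocation	12	48517177	19	30945107	PFKM (intron 3-4); ZNF536 (intron 2-3)
153T	translocation	19	30355201	X	153152399	LCA10 (intron 5-6)
153T	translocation	5	174245601	10	65204015	JMJD1C (intron 1-2)
116T	translocation	2	199768975	5	28258969
118T	translocation	7	90081994	17	25904801	KSR1 (intron 3-4)
118T	translocation	15	60231305	21	47148999	PCBP3 (intron 1-2)
118T	translocation	15	60833617	21	35917066	RCAN1 (intron 1-2); RORA (intron 2-3)
118T	translocation	15	61356378	21	41870300	DSCAM (intron 3-4); RORA (intron 1-2)
118T	translocation	15	61375512	21	27982153	RORA (intron 1-2)
118T	translocation	15	71750638	21	18023846	THSD4 (intron 6-7)
119T	translocation	2	42052196	4	66411644	EPHA5 (intron 3-4)
119T	translocation	4	4714578	17	38990874	TMEM99 (exon 3)
119T	translocation	8	32833459	18	64563574
120T	translocation	8	127068558	11	112588800
120T	translocation	11	108583473	13	21735983	DDX10 (intron 10-11); SKA3 (exon 5)
120T	translocation	13	103233303	16	77586406
148T	translocation	2	65563071	8	80378299	SPRED2 (intron 2-3)
148T	translocation	9	13526912	17	57745082	CLTC (intron 13-14)
149T	translocation	1	247997045	10	27944748
149T	translocation	3	47806974	4	151298580	LRBA (intron 48-49); SMARCC1 (intron 2-3)
149T	translocation	5	15946143	17	67928932
149T	translocation	11	108583658	13	21742368	DDX10 (intron 10-11); SKA3 (exon 4)
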
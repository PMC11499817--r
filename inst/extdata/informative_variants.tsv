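patient_id	sex	age_years	gene	transcript	hgvs_c	hgvs_p	variant_class	chrom	cnv_start	cnv_end	cnv_dosage	zygosity	origin	interpretation	clinvar_id	omim_phenotype	omim_id	omim_inheritance
3	male	2	chrXq13q21	seq[GRCh37]	dup(X)(q13q21)		CNV	chrX	69746790	80556046	DUP	Hem	maternal	P	154251	Duplication Xq13q21		XLR
4	female	4	MAF	NM_001031804	c.185C>T	p.(Thr62Met)	SNV					Het	maternal	LP	1320073	Ayme-Gripp syndrome	601088	AD
17	female	15	KAT6A	NM_006766.5	c.3385C>T	p.(Arg1129*)	SNV					Het	de_novo	P	180229	Arboleda-Tham syndrome	616268	AD
18	female	10	TECPR2	NM_014844.4	c.4006C>T	p.(Arg1336Trp)	SNV					Hom	biparental	VUS	996005	Neuropathy hereditary sensory and autonomic type IX with developmental delay	615031	AR
24	female	17	UBE3B	NM_001270449	c.61G>T	p.(Glu21*)	SNV					Hom	biparental	P	225041	Kaufman oculocerebrofacial syndrome	244450	AR
27	male	0.8	TCF4	NM_001083962	c.1165C>T	p.(Arg389Cys)	SNV					Het	de_novo	LP	1319340	Pitt-Hopkins syndrome	610954	AD
32	male	20	AHDC1	NM_001029882	c.3814C>T	p.(Arg1272*)	SNV					Het	de_novo	P	431102	Xia-Gibbs syndrome	615829	AD
35	female	0.2	chr6q24q25	seq[GRCh37]	del(6)(q24q25)		CNV	chr6	148682004	155706788	DEL	Het	de_novo	P	150766	Deletion 6q24q25	612863	AD
48	male	0.1	ABAT	NM_020686	c.168+1G>A	p.(?)	SNV					Hom	biparental	P	635252	GABA transaminase deficiency	613163	AR
64	female	13	PKD1	NM_001009944.2	c.8300G>A	p.(Arg2767His)	SNV					Het	paternal	VUS	1256450	Polycystic kidney disease 1	173900	AD
64	female	13	PKD1	NM_001009944.2	c.8291T>C	p.(Met2764Thr)	SNV					Het	maternal	VUS	976837	Polycystic kidney disease 1	173900	AD
86	male	5	KDM5C	NM_004187.3	c.860C>T	p.(Ser287Leu)	SNV					Hem	maternal	VUS	945345	Intellectual developmental disorder X-linked syndromic Claes-Jensen type	300534	XLR
87	male	23	MECP2	NM_001110792.1	c.724C>A	p.(Pro242Thr)	SNV					Hem	maternal	VUS	1439710	Intellectual developmental disorder X-linked syndromic 13	300055	XLR
95	male	15	ADGRV1	NM_032119.3	c.6994A>T	p.(Ile2332Phe)	SNV					Het	paternal	VUS	46359	Usher syndrome type IIc	605472	AR;DD
95	male	15	ADGRV1	NM_032119.3	c.17461T>C	p.(Ser5821Pro)	SNV					Het	maternal	VUS	1915342	Usher syndrome type IIc	605472	AR;DD
96	female	18	RPS6KA3	NM_004586.2	c.1269A>T	p.(Glu423Asp)	SNV					Het	maternal	VUS	1348599	Coffin-Lowry syndrome	300844	XLD
107	female	12	SKI	NM_003036	c.101G>T	p.(Gly34Val)	SNV					Het	unknown	P	39783	Shprintzen-Goldberg craniosynostosis syndrome	182212	AD
112	male	11	chr15q11q13	seq[GRCh37]	del(15)(q11q13)		CNV	chr15	22873285	28544664	DEL	Het	de_novo	P	146597	Angelman syndrome	105830	AD
115	male	23	ZBTB20	NM_001164342.2	c.1805G>A	p.(Gly602Asp)	SNV					Het	de_novo	VUS	684507	Primrose syndrome	259050	AD
132	female	15	GRIN1	NM_007327	c.1852G>C	p.(Gly618Arg)	SNV					Het	unknown	LP	981271	Neurodevelopmental disorder with or without hyperkinetic movements and seizures	614254	AD
1	female	8	DDX3X	NM_001356.4	c.1045G>A	p.(Ala349Thr)	SNV					Het	de_novo	LP		Intellectual developmental disorder X-linked syndromic Snijders Blok type	300958	XLD;XLR
2	male	25	ARID2	NM_152641.4	c.1746_1747delAG	p.(Arg582SerfsTer6)	SNV					Het	de_novo	LP		Coffin-Siris syndrome 6	617808	AD
5	female	19	TBC1D2B	NM_144572	c.274C>T	p.(Gln92*)	SNV					Hom	biparental	LP		Neurodevelopmental disorder with seizures and gingival overgrowth	619323	AR
26	male	13	NFIX	NM_002501	c.274delG	p.(Val92Cysfs*2)	SNV					Het	de_novo	LP		Malan syndrome	614753	AD
30	female	2	PUF60	NM_014281	c.1574T>A	p.(Val525Glu)	SNV					Het	de_novo	LP		Verheij syndrome	615583	AD
45	female	6	CHAMP1	NM_032436.3	c.1903_1906del	p.(Glu635Thrfs*2)	SNV					Het	de_novo	LP		Intellectual disability autosomal dominant 40	616579	AD
57	male	19	SOX10	NM_006941	c.341G>C	p.(Trp114Ser)	SNV					Het	unknown	LP		Waardenburg syndrome type 4C	613266	AD
62	female	7	SPTBN2	NM_006946.2	c.185C>T	p.(Thr62Ile)	SNV					Het	de_novo	VUS		Spinocerebellar ataxia 5	600224	AD
65	male	6	NOG	NM_005450.4	c.553T>C	p.(Ser185Pro)	SNV					Het	paternal	LP		Stapes ankylosis with broad thumbs and toes	184460	AD
67	female	7	EFTUD2	NM_004247	c.766_767del	p.(Cys256Hisfs*5)	SNV					Het	de_novo	LP		Mandibulofacial dysostosis Guion-Almeida type	610536	AD
71	male	7	SMARCA4	NM_001128844.1	c.3712T>G	p.(Ser1238Ala)	SNV					Het	de_novo	LP		Coffin-Siris syndrome 4	614609	AD
81	male	15	KANSL1	NM_001193465	c.2692A>T	p.(Lys898*)	SNV					Het	de_novo	LP		Koolen-de Vries syndrome	610443	AD
82	female	0.4	GNAI3	NM_006496	c.136A>G	p.(Lys46Glu)	SNV					Het	de_novo	LP		Auriculocondylar syndrome 1	602483	AD
85	female	12	BCOR	NM_001123385	c.4799dupT	p.(Tyr1601Leufs*7)	SNV					Het	de_novo	LP		Microphthalmia syndromic 2 oculofaciocardiodental syndrome	300166	XLD
88	male	12	ANK3	NM_020987	c.3380C>T	p.(Thr1127Met)	SNV					Het	de_novo	VUS		Intellectual disability autosomal recessive 37	615493	AR
90	female	1	SLC35A2	NM_005660	c.918_929dup	p.(Leu307_Val310dup)	SNV					Het	de_novo	VUS		Congenital disorder of glycosylation type IIm	300896	XLD
91	female	3	SETD5	NM_001080517.2	c.3196-2A>G	p.(?)	SNV					Hom	biparental	LP		Intellectual disability autosomal dominant 23	615761	AD
100	female	16	CDC42BPB	NM_006035	c.2726+1G>A	p.(?)	SNV					Het	de_novo	LP		Chilton-Okur-Chung neurodevelopmental syndrome	619841	AD
104	male	6	KMT2A	NM_001197104	c.5874_5878del	p.(Phe1959Valfs*12)	SNV					Het	de_novo	LP		Wiedemann-Steiner syndrome	605130	AD
113	female	8	DYRK1A	NM_001347721.1	c.948_949insGG	p.(Phe317Glyfs*43)	SNV					Het	unknown	LP		Intellectual developmental disorder autosomal dominant 7	614104	AD
116	female	2	CCNK	NM_001099402	c.878C>T	p.(Pro293Leu)	SNV					Het	de_novo	VUS		Intellectual developmental disorder with hypertelorism and distinctive facies	618147	AD
120	female	12	INTS1	NM_001080453.2	c.3010C>T	p.(Arg1004Trp)	SNV					Hom	biparental	VUS		Neurodevelopmental disorder with cataracts poor growth and dysmorphic facies	618571	AR
133	female	3	PDHA1	NM_000284	c.1149G>A	p.(Trp383*)	SNV					Het	de_novo	LP		Pyruvate dehydrogenase E1-alpha deficiency	312170	XLD
13	female	3	TK2	NM_001271934	c.176C>T	p.(Thr59Met)	SNV					Het	maternal	P	12710	Progressive external ophthalmoplegia with mtDNA deletions autosomal recessive 3	617069	AR
13	female	3	TK2	NM_004614	c.125_127del	p.(Asp42_Lys43delinsGlu)	SNV					Het	paternal	VUS		Progressive external ophthalmoplegia with mtDNA deletions autosomal recessive 3	617069	AR
98	male	7	MNX1	NM_005515	c.355C>A	p.(Pro119Thr)	SNV					Het	de_novo	VUS		Currarino syndrome	176450	AD
98	male	7	chr22q11distal	seq[GRCh37]	del(22)(q11.2)		CNV	chr22	21738555	22899302	DEL	Het	de_novo	P	625626	Chromosome 22q11.2 deletion syndrome distal	611867	AD
106	female	31	MECOM	NM_004991.3	c.3383G>A	p.(Cys1128Tyr)	SNV					Het	maternal	VUS	2077252	Radioulnar synostosis with amegakaryocytic thrombocytopenia 2	616738	AD
106	female	31	CAV1	NM_001753.4	c.284C>T	p.(Thr95Met)	SNV					Het	paternal	VUS		Lipodystrophy familial partial type 7	606721	AD
119	male	0.1	PCLO	NM_033026.5	c.12814C>T	p.(Arg4272Cys)	SNV					Het	paternal	VUS	1378579	Pontocerebellar hypoplasia type 3	608027	AR
119	male	0.1	PCLO	NM_033026.5	c.1656G>T	p.(Gln552His)	SNV					Het	maternal	VUS		Pontocerebellar hypoplasia type 3	608027	AR
124	female	2	ERCC6	NM_000124	c.2203C>T	p.(Arg735*)	SNV					Hem	paternal	P	1701	Cockayne syndrome type B	133540	AR
124	female	2	ERCC6	seq[GRCh37]	del(10)(q11)		CNV	chr10	49383876	52383915	DEL	Het	maternal	P		Cockayne syndrome type B	133540	AR
125	female	0.8	LRP2	NM_004525.2	c.11503C>T	p.(Arg3835Cys)	SNV					Hom	biparental	VUS	1469182	Donnai-Barrow syndrome	222448	AR
125	female	0.8	TTN	NM_001267550.2	c.30503C>A	p.(Thr10168Lys)	SNV					Hom	biparental	VUS		Muscular dystrophy limb-girdle autosomal recessive 10	608807	AR
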
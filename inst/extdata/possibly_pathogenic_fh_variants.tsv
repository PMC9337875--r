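gene	rsid	chrom	pos	ref	alt	protein_change	n_het	maf	hgmd	clinvar	lovd	hc_penetrance	cadd	novel
LDLR	rs1230170597	chr19	11089380	G	C	promoter	1	3.41e-5	NR	VUS	NR	100	20.5	0
LDLR	NA	chr19	11089574	G	A	p.Arg9His	1	3.41e-5	NR	NR	NR	100	22.8	1
LDLR	rs879254454	chr19	11102737	G	T	p.Arg88Ser	1	3.41e-5	NR	VUS	NR	100	21	0
APOB	rs267599185	chr2	21013214	G	A	p.Arg1388Cys	2	6.82e-5	NR	VUS	LB	50	20.7	0
APOB	NA	chr2	21006246	A	G	p.Ile3541Thr	2	6.82e-5	NR	NR	NR	50	23.3	1
APOB	NA	chr2	21008255	A	T	p.Asn2871Lys	1	3.41e-5	NR	NR	NR	100	22	1
APOB	rs1440306074	chr2	21012016	A	T	p.Ser1618Thr	1	3.41e-5	NR	NR	NR	100	22.8	0
APOB	rs775231207	chr2	21012456	A	C	p.Leu1471Trp	7	2.30e-4	NR	NR	NR	57	21.8	0
APOB	rs1208454201	chr2	21012474	A	G	p.Met1465Thr	2	6.82e-5	NR	NR	NR	50	21	0
APOB	rs140877474	chr2	21012493	T	C	p.Ser1459Gly	2	6.82e-5	NR	VUS	NR	50	25.5	0
APOB	NA	chr2	21015242	A	G	p.Phe1176Ser	1	3.41e-5	NR	NR	NR	100	32	1
APOB	rs765952330	chr2	21015514	C	G	p.Gly1122Arg	2	6.82e-5	NR	NR	NR	50	25.2	0
APOB	rs781511068	chr2	21023005	G	A	p.Val881Ala	2	6.82e-5	NR	VUS	NR	50	27	0
APOB	rs13306190	chr2	21032408	G	A	p.Ala433Val	4	1.36e-4	NR	LB	NR	50	24.9	0
APOB	rs12713559	chr2	21006196	G	A	p.Arg3558Cys	4	1.36e-4	DM	LP/VUS	P/VUS	50	29.5	0
PCSK9	rs185392267	chr1	55043921	C	T	p.Arg96Cys	3	1.02e-4	DM	P/LP/VUS	P/VUS	100	24.1	0
PCSK9	rs373323910	chr1	55061437	C	T	p.Arg582*	2	6.82e-5	NR	LB	NR	50	34	0
APOE	NA	chr19	44909102	G	A	p.Arg269His	1	3.41e-5	NR	NR	NR	100	24.8	1
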
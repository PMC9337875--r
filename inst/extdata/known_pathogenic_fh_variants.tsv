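gene	rsid	chrom	pos	ref	alt	protein_change	n_het	maf	hgmd	lovd	clinvar	dlcn_penetrance	hc_penetrance
LDLR	rs879254375	chr19	11089414	C	G	TF-binding	1	3.41e-5	DM	LP	VUS	100	100
LDLR	rs776421777	chr19	11100246	G	A	p.Glu31Lys	2	6.82e-5	DM	LP	LP/VUS	0	100
LDLR	rs879254420	chr19	11100324	G	A	p.Asp57Asn	1	3.41e-5	DM?	LP	P/LP/VUS	100	100
LDLR	rs730882078	chr19	11102714	C	T	p.Arg81Cys	1	3.41e-5	DM	LP	NR	0	100
LDLR	rs771019366	chr19	11102742	A	G	p.Asp90Gly	6	2.05e-4	DM	LP	P/LP	83.3	100
LDLR	rs1064793799	chr19	11102789	A	C	splice	13	4.43e-4	DM	NR	P	84.6	100
LDLR	rs730882090	chr19	11107420	C	A	p.Phe282Leu	1	3.41e-5	DM	LP	P/LP/VUS	100	100
LDLR	rs112366278	chr19	11110650	A	C	splice	1	3.41e-5	DM	LP	P/LP	100	100
LDLR	rs746834464	chr19	11110660	G	A	p.Glu317Lys	3	1.02e-4	DM?	LP	P/LP	0	33.3
LDLR	rs747507019	chr19	11110690	C	T	p.His327Tyr	4	1.36e-4	DM	LP	VUS	25	100
LDLR	rs752951310	chr19	11111598	G	T	p.Gly382Val	3	1.02e-4	DM	P/LP	P/LP/VUS	66.7	100
LDLR	rs879254809	chr19	11111607	T	G	p.Leu385Arg	1	3.41e-5	DM	LP	LP	100	100
LDLR	rs373646964	chr19	11113650	G	A	p.Asp492Asn	1	3.41e-5	DM	LP	NR	100	100
LDLR	rs758194385	chr19	11116198	A	G	p.Asn564Ser	2	6.82e-5	DM	LP	P/LP	50	50
LDLR	rs763147599	chr19	11116927	G	A	p.Gly592Arg	2	6.82e-5	DM	P	P/LP	50	50
LDLR	rs750518671	chr19	11128085	G	A	p.Val797Met	1	3.41e-5	DM	LP	NR	100	100
PCSK9	rs891322948	chr1	55059529	G	T	p.Gly516Val	2	6.82e-5	DM?	LP	NR	100	100
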
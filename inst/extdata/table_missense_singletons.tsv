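proband	chrom	pos	ref	alt	gene	transcript	consequence	cdna_change	protein_change	gnomad_af	mis_z	pli	local_tolerance	sift	polyphen	revel	gerp	dist_to_transcript_end	affects_protein_domain	splice_site_class	protein_position	inheritance	clinvar	clinvar_alt	printed_classification	kaviar_af	brain_expressed	in_segdup
01	1	53742664	G	A	LRP8	NM_001018054	missense	c.G583A	p.G195S	2.5e-05	2.77	1	highly_intolerant	D	P	0.669	2.91	NA	FALSE	not_splice	195	unknown	absent	NA	VUS	0	TRUE	FALSE
02	1	10318654	A	G	KIF1B	NM_015074	missense	c.A287G	p.Y96C	4e-06	3.6	1	intolerant	D	D	0.95	5.7	NA	FALSE	not_splice	96	unknown	absent	NA	VUS	0	TRUE	FALSE
03	4	140282956	G	T	NAA15	NM_057175	missense	c.G1618T	p.D540Y	8e-06	3.8	1	intolerant	D	D	0.54	6	NA	FALSE	not_splice	540	inherited_unaffected_parent	absent	NA	VUS	0	TRUE	FALSE
04	2	54845255	G	A	SPTBN1	NM_003128	missense	c.G688A	p.A230T	0	4.5	1	intolerant	D	D	0.86	5.6	NA	FALSE	not_splice	230	unknown	absent	NA	Likely pathogenic	0	TRUE	FALSE
04	6	165863831	A	C	PDE10A	NM_001130690	missense	c.A245C	p.Q82P	0	3.8	1	intolerant	D	D	0.53	4.6	NA	FALSE	not_splice	82	unknown	absent	NA	VUS	0	TRUE	FALSE
05	7	103124179	G	A	RELN	NM_005045	missense	c.G10102A	p.G3368R	5.7e-05	1.14	1	intolerant	D	D	0.703	5.72	NA	FALSE	not_splice	3368	unknown	conflicting	likely_benign	VUS/likely benign	0	TRUE	FALSE
05	10	27405184	G	A	YME1L1	NM_001253866	missense	c.G1711A	p.E571K	0	2.06	0.99	intolerant	D	D	0.943	5.43	NA	FALSE	not_splice	571	unknown	absent	NA	VUS	0	TRUE	FALSE
05	12	49333815	G	C	ARF3	NM_001659	missense	c.G224C	p.R75P	0	3.01	0.62	highly_intolerant	D	D	0.881	3.83	NA	FALSE	not_splice	75	unknown	absent	NA	Likely pathogenic	0	TRUE	FALSE
05	14	35240770	C	T	BAZ1A	NM_182648	missense	c.C3152T	p.A1051V	4e-06	2.69	1	intolerant	T	D	0.636	5.66	NA	FALSE	not_splice	1051	unknown	absent	NA	VUS	0	TRUE	FALSE
06	19	42777266	G	T	CIC	NM_001304815	missense	c.G1331T	p.C444F	0	1.53	1	NA	NA	NA	NA	4.7	NA	FALSE	not_splice	444	unknown	absent	NA	VUS	0	TRUE	FALSE
07	9	140069703	G	A	ANAPC2	NM_013366	missense	c.G2242A	p.E748K	4e-06	2.43	1	intolerant	D	D	0.506	4.32	NA	FALSE	not_splice	748	unknown	absent	NA	VUS	0	TRUE	FALSE
07	19	41183304	T	C	NUMBL	NM_001289979	missense	c.T440C	p.V147A	0	3.18	1	intolerant	D	D	0.596	5.31	NA	FALSE	not_splice	147	unknown	absent	NA	VUS	0	TRUE	FALSE
08	5	45695972	G	GGCGGCGGCG	HCN1	NM_021072	inframe_indel	c.223_224insGCGGCGGCG	p.G74_E75insGGG	7.2e-05	3.72	1	intolerant	NA	NA	NA	NA	NA	FALSE	not_splice	74	unknown	likely_benign	NA	Likely benign	0	TRUE	FALSE
08	12	122626291	C	G	MLXIP	NM_014938	missense	c.C2692G	p.P898A	0	1.87	0.98	intolerant	D	D	0.72	5.5	NA	FALSE	not_splice	898	unknown	absent	NA	VUS	0	TRUE	FALSE
09	9	130422360	C	T	STXBP1	NM_001032221	missense	c.C298T	p.R100W	7.1e-06	4.3	1	intolerant	D	D	0.7	4.6	NA	FALSE	not_splice	100	unknown	conflicting	likely_pathogenic	Likely pathogenic/VUS	0	TRUE	FALSE
09	10	75557014	CAAG	C	ZSWIM8	NM_001242487	inframe_indel	c.3403_3405del	p.K1137del	1.8e-05	5.53	1	intolerant	NA	NA	NA	NA	NA	FALSE	not_splice	1137	unknown	absent	NA	VUS	0	TRUE	FALSE
10	11	120312519	C	A	ARHGEF12	NM_001198665	missense	c.C1139A	p.A380E	0	3.3	1	highly_intolerant	D	D	0.82	5.5	NA	FALSE	not_splice	380	unknown	absent	NA	VUS	0	TRUE	FALSE
10	20	50307357	A	G	ATP9A	NM_006045	missense	c.A644G	p.D215G	2.1e-05	4.2	1	intolerant	D	D	0.79	5.3	NA	FALSE	not_splice	215	unknown	absent	NA	VUS	0	TRUE	FALSE
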
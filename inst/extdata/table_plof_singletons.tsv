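proband	chrom	pos	ref	alt	gene	transcript	consequence	cdna_change	protein_change	gnomad_af	pli	mis_z	local_tolerance	sift	polyphen	revel	gerp	dist_to_transcript_end	affects_protein_domain	splice_site_class	protein_position	inheritance	clinvar	clinvar_alt	printed_classification	kaviar_af	brain_expressed	in_segdup
01	16	30991037	ACCCTGCGCCAG	A	SETD1A	NM_014712	frameshift	c.3930_3940delCCCTGCGCCAG	p.P1313Afs*17	0	1	NA	NA	NA	NA	NA	NA	1182	TRUE	not_splice	1313	inherited_affected_parent	absent	NA	Pathogenic	0	TRUE	FALSE
02	2	242122172	GC	G	PPP1R7	NM_002712	frameshift	c.1017delC	p.R340Gfs*111	0	0.99	NA	NA	NA	NA	NA	NA	60	FALSE	not_splice	340	inherited_unaffected_parent	absent	NA	VUS	0	TRUE	FALSE
04	5	145859585	CTAGTTA	C	TCERG1	NM_006706	splice	c.1820-3_1822delTAGTTA	NA	2.2e-05	1	NA	NA	NA	NA	NA	NA	NA	FALSE	main_donor_acceptor	NA	unknown	absent	NA	VUS	0	TRUE	FALSE
06	16	67580073	C	G	RIPOR1	NM_024519	stop_gain	c.C3501G	p.Y1167X	0	0.95	NA	NA	NA	NA	NA	NA	300	TRUE	not_splice	1167	unknown	absent	NA	VUS	0	TRUE	FALSE
06	17	38572722	TG	T	TOP2A	NM_001067	frameshift	c.220delG	p.E74Kfs*16	0	0.99	NA	NA	NA	NA	NA	NA	4371	TRUE	not_splice	74	unknown	absent	NA	VUS	0	TRUE	FALSE
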
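gene	established_ndd_gene	lof_mechanism	missense_mechanism	causal_clusters	domain_critical	phenotype_similarity	notes
SETD1A	TRUE	TRUE	FALSE		FALSE	overlapping	haploinsufficiency disorder incl. speech phenotypes
SPTBN1	TRUE	TRUE	TRUE	173-284	FALSE	overlapping	missense cluster in second calponin homology domain
ARF3	TRUE	FALSE	TRUE	70-85	FALSE	overlapping	switch-2 domain, GTP/GDP binding
NAA15	TRUE	TRUE	TRUE	450-484	FALSE	overlapping	causal missense variants concentrate in aa 450-484
RELN	TRUE	FALSE	TRUE		FALSE	overlapping	
CIC	TRUE	TRUE	TRUE	200-269	FALSE	overlapping	HMG-box domain cluster
STXBP1	TRUE	TRUE	TRUE		FALSE	overlapping	
HCN1	TRUE	FALSE	TRUE		FALSE	overlapping	
KIF1B	TRUE	FALSE	TRUE		FALSE	dissimilar	Charcot-Marie-Tooth type 2A1
PDE10A	TRUE	FALSE	TRUE		FALSE	dissimilar	infantile striatal degeneration
LRP8	FALSE	FALSE	FALSE		FALSE	unknown	
YME1L1	FALSE	FALSE	FALSE		FALSE	unknown	
BAZ1A	FALSE	FALSE	FALSE		FALSE	unknown	
ANAPC2	FALSE	FALSE	FALSE		FALSE	unknown	
NUMBL	FALSE	FALSE	FALSE		FALSE	unknown	
MLXIP	FALSE	FALSE	FALSE		FALSE	unknown	
ZSWIM8	FALSE	FALSE	FALSE		FALSE	unknown	
ARHGEF12	FALSE	FALSE	FALSE		FALSE	unknown	
ATP9A	FALSE	FALSE	FALSE		FALSE	unknown	
PPP1R7	FALSE	FALSE	FALSE		FALSE	unknown	
TCERG1	FALSE	FALSE	FALSE		FALSE	unknown	
RIPOR1	FALSE	FALSE	FALSE		FALSE	unknown	
TOP2A	FALSE	FALSE	FALSE		FALSE	unknown	
KDR	FALSE	FALSE	FALSE		FALSE	unknown	
RPL31	FALSE	FALSE	FALSE		FALSE	unknown	
STAB1	FALSE	FALSE	FALSE		FALSE	unknown	
TMEM86A	FALSE	FALSE	FALSE		FALSE	unknown	
ADAMTS18	FALSE	FALSE	FALSE		FALSE	unknown	
PGLS	FALSE	FALSE	FALSE		FALSE	unknown	
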
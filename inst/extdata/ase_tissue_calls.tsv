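# Per-gene allele-specific-expression outcomes for the 21 genes carrying a
# monoallelically methylated SNP that reached the coverage thresholds in
# 16 normal-tissue RNA-seq data sets (published discovery study; one row per
# gene x expression type, n_tissues = number of tissues with that call).
gene_id	gene_symbol	classification	n_tissues
ENSG00000219438	FAM19A5	ASE	1
ENSG00000184985	SORCS2	ASE	1
ENSG00000169604	ANTXR1	ASE	1
ENSG00000255339	NDUFB8	ASE	1
ENSG00000166136	NDUFB8	ASE	10
ENSG00000130600	H19	ASE	10
ENSG00000175643	RMI2	ASE	1
ENSG00000175643	RMI2	BE	1
ENSG00000122390	NAA60	ASE	1
ENSG00000122390	NAA60	BE	10
ENSG00000138641	HERC3	ASE	1
ENSG00000138641	HERC3	BE	4
ENSG00000155093	PTPRN2	ASE	1
ENSG00000155093	PTPRN2	BE	1
ENSG00000182093	WRB	ASE	2
ENSG00000182093	WRB	BE	7
ENSG00000198300	PEG3_ZIM2	ASE	2
ENSG00000198300	PEG3_ZIM2	BE	1
ENSG00000183486	MX2	ASE	2
ENSG00000183486	MX2	BE	4
ENSG00000130844	ZNF331	ASE	2
ENSG00000130844	ZNF331	BE	1
ENSG00000074181	NOTCH3	ASE	4
ENSG00000074181	NOTCH3	BE	6
ENSG00000214265	SNURF	ASE	4
ENSG00000214265	SNURF	BE	2
ENSG00000128739	SNRPN	ASE	7
ENSG00000128739	SNRPN	BE	1
ENSG00000100138	NHP2L1	ASE	8
ENSG00000100138	NHP2L1	BE	7
ENSG00000087460	GNAS	ASE	13
ENSG00000087460	GNAS	BE	1
ENSG00000235590	GNAS_AS1	BE	1
ENSG00000087116	ADAMTS2	BE	3
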
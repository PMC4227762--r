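# Record counts at each stage of the published 334-sample MethylCap-seq
# discovery analysis (as printed): candidate mismatch positions overlapping
# the known-SNV catalogue, loci retained by the MAF < 0.9 and total-coverage
# (>= 350 autosomes / >= 250 chrX) filters, loci passing the stage-1 gate
# (P <= 0.005 at 1000 iterations), and loci significant at FDR 0.1 after
# stage 2 (1,000,000 iterations).
stage	count
dbsnp_overlap	19850891
filter_retained	486090
stage1_pass	1757
significant	80
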
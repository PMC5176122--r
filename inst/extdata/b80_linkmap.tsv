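# B80 haplotype to SRK allele associations from the population survey.
# hap43 associates with more than one SRK background.
b80_hap	srk_alleles
hap75	S19
hap76	S19
hap49	S19
hap114	S19
hap50	S1
hap115	S1
hap78	S1
hap67	S1
hap51	S1
hap48	S3
hap30	S13
hap90	S20
hap43	S1,S27
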
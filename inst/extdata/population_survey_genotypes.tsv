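# Per-individual S-locus genotypes for the ten populations whose tallies are
# fully determined by the published population survey (8 individuals each).
# Genotypes are in OBSERVED form, as allele-specific PCR reports them: a
# single amplified allele plus an unidentified copy ("?") with the B80
# genotype carrying the information needed to resolve homozygotes.  The
# pairing of alleles into individuals within a population is one fixed
# arrangement consistent with the published per-allele individual counts,
# heterozygosity and homozygote calls; any such arrangement gives the same
# population tally.  S45 (SBD_6) is an amplicon unlinked to the SI phenotype
# and is excluded from tallies via the exclusion list.
individual	population	srk_alleles	b80_alleles	phenotype
TC_1	TC	S19,?	hap75,hap75	SC
TC_2	TC	S19,?	hap75,hap75	SC
TC_3	TC	S19,?	hap75,hap75	SC
TC_4	TC	S19,?	hap75,hap75	SC
TC_5	TC	S19,?	hap75,hap75	SC
TC_6	TC	S19,?	hap75,hap75	SI
TC_7	TC	S19,?	hap75,hap75	SC
TC_8	TC	S3,S19	NA	SC
TCA_1	TCA	S19,?	hap75,hap75	SC
TCA_2	TCA	S19,?	hap75,hap75	SC
TCA_3	TCA	S19,?	hap75,hap75	SC
TCA_4	TCA	S19,?	hap75,hap75	SC
TCA_5	TCA	S19,?	hap75,hap75	SC
TCA_6	TCA	S19,?	hap75,hap75	SC
TCA_7	TCA	S19,?	hap75,hap75	SC
TCA_8	TCA	S19,?	hap75,hap75	SC
PTP_1	PTP	S1,?	hap50,hap50	SC
PTP_2	PTP	S1,?	hap50,hap50	SC
PTP_3	PTP	S1,?	hap50,hap50	SC
PTP_4	PTP	S1,?	hap50,hap50	SC
PTP_5	PTP	S1,?	hap50,hap50	SC
PTP_6	PTP	S1,?	hap50,hap50	SC
PTP_7	PTP	S1,?	hap50,hap50	SC
PTP_8	PTP	S1,?	hap50,hap50	SC
WAS_1	WAS	S1,S19	NA	SC
WAS_2	WAS	S1,S19	NA	SC
WAS_3	WAS	S1,S19	NA	SC
WAS_4	WAS	S1,S19	NA	SC
WAS_5	WAS	S19,?	hap75,hap75	SC
WAS_6	WAS	S19,?	hap75,hap75	SC
WAS_7	WAS	S19,?	hap75,hap75	SC
WAS_8	WAS	S19,?	hap75,hap75	SC
RON_1	RON	S1,?	hap50,hap50	SC
RON_2	RON	S1,?	hap50,hap50	SC
RON_3	RON	S1,?	hap50,hap50	SC
RON_4	RON	S1,?	hap50,hap50	SC
RON_5	RON	S1,?	hap50,hap50	SC
RON_6	RON	S1,?	hap50,hap50	SC
RON_7	RON	S1,?	hap50,hap50	SC
RON_8	RON	S1,?	hap50,hap50	SC
KTT_1	KTT	S19,?	hap75,hap75	SC
KTT_2	KTT	S19,?	hap75,hap75	SC
KTT_3	KTT	S19,?	hap75,hap75	SC
KTT_4	KTT	S19,?	hap75,hap75	SC
KTT_5	KTT	S19,?	hap75,hap75	SC
KTT_6	KTT	S19,?	hap75,hap75	SC
KTT_7	KTT	S19,?	hap75,hap75	SC
KTT_8	KTT	S19,?	hap75,hap75	SC
LPT_1	LPT	S19,?	hap76,hap76	SC
LPT_2	LPT	S19,?	hap76,hap76	SC
LPT_3	LPT	S19,?	hap76,hap76	SC
LPT_4	LPT	S19,?	hap76,hap76	SC
LPT_5	LPT	S19,?	hap76,hap76	SC
LPT_6	LPT	S19,?	hap76,hap76	SC
LPT_7	LPT	S19,?	hap76,hap76	SC
LPT_8	LPT	S19,?	hap76,hap43	SC
PIN_1	PIN	S1,S3	NA	SI
PIN_2	PIN	S1,S19	NA	SI
PIN_3	PIN	S1,S19	NA	SI
PIN_4	PIN	S1,S19	NA	SI
PIN_5	PIN	S1,S39	NA	SI
PIN_6	PIN	S1,S39	NA	SI
PIN_7	PIN	S1,S39	NA	SI
PIN_8	PIN	S20,S39	NA	SI
OWB_1	OWB	S1,S13	NA	SI
OWB_2	OWB	S1,?	hap50,hap50	SI
OWB_3	OWB	S1,?	hap50,hap50	SI
OWB_4	OWB	S1,?	hap50,hap50	leaky
OWB_5	OWB	S1,?	hap50,hap50	SI
OWB_6	OWB	S1,?	hap50,hap50	SC
OWB_7	OWB	S1,?	hap50,hap50	SI
OWB_8	OWB	S1,?	hap50,hap50	SI
SBD_1	SBD	S1,?	hap115,hap115	SI
SBD_2	SBD	S1,S3	NA	SI
SBD_3	SBD	S1,S3	NA	SI
SBD_4	SBD	S1,S3	NA	SI
SBD_5	SBD	S1,S3	NA	SI
SBD_6	SBD	S13,S45	hap30,hap43	SI
SBD_7	SBD	S19,?	hap49,hap50	SI
SBD_8	SBD	S20,?	hap90,hap78	SI
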
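# Population metadata: multilocus outcrossing rate (Tm), genetic cluster and
# mating class.  TCA's outcrossing-rate estimate is based on few families and
# is excluded from group Tm means (tm_excluded).
population	tm	cluster	mating_class	tm_excluded
TC	0.18	1	inbreeding	FALSE
TCA	0.48	1	inbreeding	TRUE
PTP	0.02	2	inbreeding	FALSE
WAS	0.25	2	inbreeding	FALSE
RON	0.28	2	inbreeding	FALSE
KTT	0.31	3	inbreeding	FALSE
LPT	0.13	4	inbreeding	FALSE
PIN	0.84	2	outcrossing	FALSE
OWB	0.64	5	outcrossing	FALSE
SBD	0.94	5	outcrossing	FALSE
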
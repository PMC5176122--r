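# Example silique counts from replicate self-pollinations.
plant_id	full	partial	empty
F2_001	6	0	0
F2_002	0	0	6
F2_003	0	2	4
F2_004	4	1	1
F2_005	5	0	1
F2_006	0	1	5
F2_007	1	3	2
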
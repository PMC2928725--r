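#id	chr1_1	chr1_2	chr2_1	chr2_2
ind_1	0	1	2	0
ind_2	1	1	0	0
ind_3	2	0	1	1
ind_4	0	2	1	0
ind_5	1	0	0	2
ind_6	2	1	2	1
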
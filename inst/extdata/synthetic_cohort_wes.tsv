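patient	source	TET2	RHOA_G17V	DNMT3A	IDH2_R172	chr5_gain	chr7_gain	chr19_gain	chr21_gain	chr22q_gain
P01	WES	1	1	0	1	1	0	0	1	0
P02	WES	1	1	0	1	1	0	0	0	0
P03	WES	1	1	1	0	1	0	0	0	0
P04	WES	1	1	1	0	1	0	0	0	0
P05	WES	1	1	1	0	1	0	0	0	0
P06	WES	1	1	1	0	0	1	0	0	0
P07	WES	1	0	1	0	0	1	0	0	0
P08	WES	1	0	1	0	0	0	1	0	0
P09	WES	1	0	0	0	0	0	1	0	0
P10	WES	1	0	0	0	0	0	0	1	0
P11	WES	1	0	0	0	0	0	0	0	1
P12	WES	0	0	0	0	0	0	0	0	1
P13	WES	0	0	0	0	0	0	0	0	0
P14	WES	0	0	0	0	0	0	0	0	0
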
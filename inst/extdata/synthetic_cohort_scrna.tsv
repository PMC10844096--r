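patient	source	chr5_gain
P01	scRNA	1
P02	scRNA	1
P03	scRNA	1
P04	scRNA	1
P05	scRNA	1
P06	scRNA	1
P07	scRNA	0
P08	scRNA	0
P09	scRNA	0
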
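species	13.2	15.0	17.2	19.2	21.0	25.1	36.2	38.0	42.0	57.0	57.2	59.0
sp01	1	1	1	1	1	1	0	1	0	0	1	1
sp02	0	1	1	1	1	1	1	1	0	1	1	1
sp03	0	1	1	1	1	0	1	1	1	1	0	1
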
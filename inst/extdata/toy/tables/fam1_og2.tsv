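species	10.0	14.2	16.0	17.0	19.1	26.2	38.2	51.0	57.2	58.0	59.0
sp01	0	1	0	1	0	0	1	1	1	1	1
sp02	0	1	1	0	1	1	1	1	1	1	0
sp03	1	1	1	1	1	0	1	1	0	1	0
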
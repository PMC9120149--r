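species	10.0	13.2	14.0	16.2	26.1	38.1
sp01	1	1	0	1	1	1
sp02	1	1	0	1	1	1
sp03	1	0	1	1	1	1
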
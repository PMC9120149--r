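species	10.0	14.0	16.2	20.0	24.1	25.1	26.1	38.1	48.1	54.1	56.0
sp01	0	0	1	1	1	1	1	0	1	1	0
sp02	1	0	1	1	1	0	0	0	0	1	0
sp03	0	1	1	1	1	0	1	1	1	1	1
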
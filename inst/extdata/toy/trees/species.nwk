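((sp01:0.3563359745,sp02:0.5851271811)speciation:0.782124293,sp03:0.4958618733)speciation;
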
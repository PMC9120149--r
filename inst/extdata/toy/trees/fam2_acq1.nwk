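(fam2_og1,fam2_og2)duplication;
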
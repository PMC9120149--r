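>sp01|fam2_og2
MPQGNEWYPNDNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
>sp02|fam2_og2
MPQGNEWYPNVNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
>sp03|fam2_og2
MPRGNEWYPNVNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
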
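>sp03|fam1_og1
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp03|fam1_og2
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp03|fam2_og1
MPQGNEWYPNVCPVEDWCEMQDDVADIKCEDVECSFAYGYYWGPHKICPHWPMCVSGEEN
>sp03|fam2_og2
MPRGNEWYPNVNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
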
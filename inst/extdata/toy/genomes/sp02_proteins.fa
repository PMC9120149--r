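>sp02|fam1_og1
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp02|fam1_og2
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp02|fam2_og1
MPQGNEWYPNVNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
>sp02|fam2_og2
MPQGNEWYPNVNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
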
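>sp01|fam1_og1
MALLSSRQHNFSCYNHNNLKFFRFDFGHLCTASYRYTDQSATKLSMPITSLQEHDCIAKM
>sp01|fam1_og2
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDAIAKM
>sp01|fam2_og1
MPQGNEWYPNVNPVEDWCEMQDDVADIKCEDVECSSAYLYYWGPHKICPHWPMCVSGEEN
>sp01|fam2_og2
MPQGNEWYPNDNPVEDWCEMQDDVADIKCEDVECSFAYLYYWGPHKICPHWPMCVSGEEN
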
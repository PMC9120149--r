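>sp01|fam1_og1
MALLSSRQHNFSCYNHNNLKFFRFDFGHLCTASYRYTDQSATKLSMPITSLQEHDCIAKM
>sp02|fam1_og1
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp03|fam1_og1
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp01|fam1_og2
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDAIAKM
>sp02|fam1_og2
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
>sp03|fam1_og2
MALLSSRQHNFSCYNHNNLKFFRFDYGHLCTASYRYTDQSATKLSMPITSLMEHDCIAKM
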
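>sp01_fam1_og1
GGTGACCCCCTCACAATACAATGGCATTGTTGAGCTCACGTCAACACAACTTTAGTTGGTTTTGCGCATTTTCCCATAGT
GGGACCTTCGACCCGCCAACGCGGTTCGCGGCGGCCTTGCCCCTACTAAGCTACGTTGTATCGCTAACGCGCCTGGCTCG
CCGTACCTCTCGATACCTGGCCTGAGGTCCGTAACAATCCGTACAACGCGGGCTATAGAATCATAAGTATTACACACAAT
AGTTTACAGCGATACTTCATCGATGCCCAACATTATGTGTCAGAAAGATAGCAATCTGTGCGGCAACATATTCGAGTTGA
TTCCCTTTTGGACAAAAAGGGGTTCATCTATCGCGAGCAAAGTATCTTTATTTCCGGGCATGGCAAGTGCAAATCGTGCC
ATTTAGAGAAGGCAAGTTGCTGTATGTAAAGTTCTTCCGGTTTGGTTACAGGCGCCCCCGTGGTACGGGATGTTGTTCAG
GTATGAAGCGAACGAGCACAGAAGGTTTTGAGCTTGCAGACTTCGGTCATCTCTGTACAGCCTCTTATCGTTATACTGTA
CGCACCAAGGTCTCCGCACACACAGATCGATTCTAGTTTGCTTGCAAGCTTAGGGGTCGTGAAGAACGCCAACTTTCCTT
GATGTGTGTGCTCAGAACGCTACATCACAACTCTAGGATCAGAGTGCTACCAAGTTGAGTATGCCGATTACGAGCTTACA
AGAACACGATTGCATGTGTATTACTACATCTGCTGCTAAGAAAGGCGGAGAGTTACCCTACATCTTTTATGCTTAGTGCC
GTATGTGTGCACCTGATGATGACGCATTCTTCGGTCACCAGACAAATTCCCGTTGCTTGCTCGACACCTACGAGGATTGG
GTGCGGAACACTCTTGAGAAAATGTAAATAACTACTGACCGCACTCT
>sp01_fam1_og2
CTGTCCTCCACCATTGTCCATTACATTTTCTCTAAGCTAAGTAGCTGGGCTATGCGATCTTCTTCCAACATAGTTAGACG
ATTGAAACCGTCTAATTCCTGACCGCCTACAGCAATCAGGTGTATCTGGGAACAAACGCTTGGCCTATCGAAGGGAACGA
TTAGATAGATTCCAGCTCCGGTCTTTACCATCGGCGCAACGCTCAAGGACCAGGCGTGGTTTCCTTTTCCACCTTGTAAG
TAATCTTTCGTAAGAGTTTTACGAAACATCGCGTCATGCTCCATCAGCTCATTTGTGTTAAGGAACAGGTATCATTAAAA
GGTCAGCGATCTGCAGCTAAGTAGCTTGTTCCCGTAGGTATCGCTGCACTGAAGTAATCGGCATTGATAGTTTAGTGGCG
GATTGACTGGGCTCAGAATCCTTACCCGTGTCGTTATAATGCTTTTGTTCGCAATTATCGGGTTGCTATTGGGGGGTTAG
CAGGTTTATTCCGGGTGAATCGAGCCATATGGCTAGACTCAGTATATCTGTAACTGGCGGTACATAAGTGCCCATAATCG
AAACGAAAGAACTTAAGATTGTTCTTGATAGCGACTTTTCGCAAGGTCTTCAGTGCGGAGGTACCAGTGAATAGCGCACT
TACCACTCGTTCGGTGACTACGTGATTGCTGGTGCATTCGATGCCTTTCGCCTGCGGAGAGGATGACCCAGATGAGGAGC
TCTAGATTTGATGTCAAGCACGTGTGCGTTAAGCGTGCATCAAGCTTCTAACTAACAAGAGAAGTTGTGCTGCCTGGAAC
TTAAGAGTGCCATGATCTAACTTGACGCTGGAT
>sp01_fam2_og1
TCTAACGAAGGTTGTTTCTCTTAATTCTCCTCCCCACTGACGCACATCGGCCAATGAGGACAGATTTTGTGTGGCCCCCA
GTAGTACAAGTCTACGAGGGTTATCCACCTTACTCAAATAGCGTCGTTAGCTCTCTTTAAGGCCTTTATATGAGCGAACC
TAGGAGGGCGAGATTCGGTGGGCCGTCACCAGAGCCCTCTGATTGACCACAGGCACTCGAACACTCCACATCCTCGCACT
TGATATCTGTGGACATGCAGACTTGTACATGGGGCTAAGTTAACGTTGTAGGCGGACCCATACTGGTGGTAGGAACCGGC
CTTTGTATGGGCACATGACGCTCATCTCGAACCCGCGACATCATCCTGCATTTCACACCAACTAAAATTTCAGCCGGCCG
GAAGATTAGAGATGAGTATATCCTCAATTCTCCAGGAATAGGCGTGCCCACGTCAAGACGACGTGCTGTAATTTCATCTA
GTAGAATAGACTCCTCGACACTGTCAAGTGGCATCCGGCAATCAATGTAGGTCGTTAAACGCCACCATATGCGCGTGTAC
CAGTTCCTTCTAATTTACGGCTCAGGCGGGACGGATTCACATTCTGTCAATATAGTGCTGCTAGTCAGATCAGTCTTGAC
CTTAAGCCTTATCTAGTGCTCCAAAACTGTACTCCCGGTTTGTTAGAGACTTGCAGGCACCACCCTTACCGGGTACCACT
CGTTCCCTTGGGGCATTCGGGACGCTGCACCAACGG
>sp01_fam2_og2
AGATCAATATATTGCTCTAAATGCCGCAGGGAAATGAGTGGTATCCTAATGATAACCCCGTCGAGGAGTAAATAAAAATA
CCCGCCGCGACGTCCGAAGGTCCCGTAAACTAGTCTAGGGGGTGCTATCCGGAGTTGCAGGGAAGTTGGTGTGAGGTCAG
AACCTTCCGCGCGTCAGAGAAAGGCCATTTCCTCGCAACTTTGCGACGTGTTAGTCTGTAATAGCCCGCTGCCTGAACAA
CCCGGGATCCCTACCATACTCTATGAGATGCAGGATGACGGTATATTAGTTTTACACCGTTTATTTGAGACCTAGGGAAA
CCTTCTGACCCAGTACATAAGGTTCGCCGTTAAGATGATAGTGGGTCCAGACAAATAATATGCCTAGTCTCGTCTTTGCT
ATTAGTTATTTCAGTAGGAACAATTGTGAAGTAGCGGGTCCGGTCAATAGCCATAGTCTAAGCCTTGACCAACTCTCTTT
CCATGAGAGGAAAGTCGTGTACGGTCGTAGGCTAAAGATATAAAATGCGAGGACGTGGAGTGCTCGTTTGCCTACCTATA
CTACTGGGGCCCACACAAGATCTGTAGTTATATCTGTCGACATCCGAAGCGACCGCTTCGCTTGTATGGCAACTTTGGCG
GTTGTGCTCACGCCGTCAGACATAAAGTGAGGCTGAGCCAGGTCCCCACTGGCCGATGTGTACGCTGTCCCGCGGCACAT
GTCGGTCCAATAGTAGCCCTAGCTCCTTTATCGGCTGAAAGGCCACTTGCAGTCTTGAGCTACCCTTTTCTGCCGAGGGA
CAATGGTAGGCGTTAGCGGTGAGGAAAATTAAACTTCACTCGGTCGTAGAAT
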
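>sp03_fam1_og1
TGTCGGTTCCTACCGTGCTATTACATTTTCTGACCCTTCCAATGCGATGACTGATAGCACCCTCACCAAACTTTCCTAAT
CATCGTTAGTGTCGCTAGGGAGAGTAATTAACTGCTATCTGGATGCCCCGTCGTACAAATTTTACTGGGAGGGCCGTGGG
CGAAGATCATACCGGTTTTGGTCGGATGCAATAGCCGTGGGTCAACCGTAGGGGTCGAACGCAGTCGTGTTCCATTAAGC
TGGTAATAGGCATTGATAATTTGGTCTTCCAATTTGTTGAGTCCAAGTTGGAAGCACGCGATGAGCTGTGAACCTACGCA
AGCCATCACAGTGACAGACTGCTGCGCAGCACTCACACGGCCGATTGATCCTTGAAACAGTGGATCCCATGGACCGAGAA
ATGAGAGTCAGACGCTGACCTACGTGTTACACGGCGTGTGTGTCTGCCCTACGATTGGTGAAGGTCCTTCTCTATCGACT
GGTTACGTACAGTACTCAGCTGTCCCGGAGCGAGCGTTTGTCCTGCTGGGTTCTCCGGGCCGGATTCGGGATATAAGCAA
CTGGAGGTTCAGGTCGCAGCTCACAACTTACAGCTGTTTATATCCATACACTATCTATATGACGCTGTACATAGATGGCC
GTAATCAAAGCGGAAAAACTTTATGTATGTCAGCTGAAGAGTCTTCAATACAACAATGAGACGGGTTTTTAAAGTTGAGA
CCTTGCTGGCCATGCGAATCCATGAAACGAAACTGCCACAGAGGTTAGCTACGTGAGTTGGGCGTTCAGCACTTTACGCA
TCGTGGCGCGGTTCGCCTCTATTCACTCGCATCCTTGTCCGGGACAGATTGCTATTTTAGGTAACCAGCACATGAAAAAA
CCTATGGTGGTCCACTATTCGGCGATCGGGTCATCATGCCGGCCCCGCACGCATCCAAACATCCTATTACTTGTGGTTCT
TTACGGCGGTATAATAGGGTGAACATGACGTCGCACTGAATGGATGTTTGCGCTACCCGACAGGCTGTTAGGGGACCCTA
TGGCAATCGGTACAACATAGCAGGAAAAGTTATGTTGACGTGAGGACAGTAGCGCCATAGCGAACCTTAGCTCGGTAT
>sp03_fam1_og2
TCCTATCTCTCACGCTTGAAATGGCGCTCCTAAGCTCTCGCCAACATGTGATGCTCAGTAGTACCTGTTGTGAGAGGCCT
TACGCCAGAGGAAAACTAGTATCTATGCCCGCACGAAAGAGAACTTCAGTTGCTAGTGGTGCATTTCAAAACGCGCCTGG
TGGAACCTAGCACCGTCGTTCTTGAGCAGCTGATTGATTCCTCCCGTCTATTGGACTGTTTATATCGACTGTCGAGCAAC
GTACTGCACCCCATTACATTTACACATGCATCCCGCTCTACTAAACAGAGCGCCGGGCCGAATCAACAGCGCGGTCCTTG
CAGAGTTTGGTGGAGAAAGGAAGTTTCCGTAGCACGTTGTCCCTCAGTCCCGCAAGTAGTAGGTTTCCGGAGATCGGCTG
CGTCCTCCACGAGCCGAGACGCAATTCAGAATAACTGTATACGCACTTCATCGCCTTTTCGTGTGCCGAGCCTCGTTCAG
CGAGAGAATACCATTCACCGATTTGAGGTAGAACTGATGAACAGGCGCCCTAACATAGTGAAGTTTTTCAGATTTGATTA
CGGCCATCTTTGTACAGCGTCCTATCGATACACAGAGTCTGCCTTGCCTGTGAGCAATCGATGCCTCACTGCATCCGCGC
CCCCTAGTTGTATGACGCGGAGCTTACTTATAGCCGCGCCGATGACGACCCTACGGCCGGCTCCATTCGAGCCAGTCGGC
TACTAAGCTGAGTATGCCCATAACCTCAGTGGAAGAAACTTCTGCAGAAGGAGTCTAGAGTAGAATCCACACCGATTATG
AAGAGCAGCCACCAGCGACGCACCTACAAGCTGACAAGAAGGAGAAGTTAATGGAGCACGACTGTATTGTCTATAGTAGA
TTGCGGGGGTCCTTTTTCCCGCTAAAGAGTTAAGCAATCAGACGCAGCAATAGGCTAAAATGTAAAAACAGAACTGTCGT
TGACC
>sp03_fam2_og1
TACCCCACTTAGGTCTCCTATTAATTTTCCTCTCCAGATACACACATTGGCCAATGAGGGCAAATCTTGTGTGGCCCCCA
ATAATACCCATCTCGGAGCCTTAATTCTAGAGCGAAAGTTTTTAGCCGTCAGAGACGATTTCAAGGTTGCACATGCAAAT
GAGCACTCTACGTCCTCGCATTTTATATCTCGACCTCTGCTATTGGGCCTCCCATAGGGAATATCAGCGTGGAGCGCCGT
TCGCGGAAGCACCGGCTACGTCGTCCTGCATCTCGCACCAACTTAGTATCTCCAAGTACACATGCCAACAGGTATGCTAC
CCTCTATCACCGTTTAACACCTGAGAGGAGTCCTTTGACTCCTCCACCTCCCAAACGTCACGCGATACCCGCGTAACCCA
CAGGGTTCCGTCAGACCCGCCTCTAAGTGCGGGGGGTGGACGGAGCAGGATCATACTCACAGGACAGACATTCTTTGTTA
ACTTCGCGATAGTAACTTTCACTTTTACGTTAACAGCAGCTAGAGAAGCGTGACTTTTGTTCATGACCTTAATGTATTGT
GAAACAGGATACCACTCGTTGCCTTGTGGCATCAACTGCGTTAAGAACGAAC
>sp03_fam2_og2
ATTAGACGAGGTCGGCCTTATTAGTTTTCTTCTCCGCTCTCATGACGACGGCCTATGTCTTGATGTTATGCACATGCGAC
GACGGACTTGTCGTGCCACGAGGTCAGATTATACTAGTATCTGTTGACTAGCGACAGTCGCGCGCCACGACGCCTGTCGG
ATTTGCGTGATTTTGAAGGCGACGGTAACCCTGCCAAAGTATGCGGGTGTGGTCTCGGCGTTTAAGATCAGCCGAGGATT
AGACCTACATCTGCGCCTAAACACATCGGCCAGTGTGGACCTTGATTCCGAAGTATTCTATTGATCCTTAAATTTGTGAT
CCTCGGCGAGAGAACTTCAGCGGGACAAGGGGGAAACATATTTTATGTGGACCCCAATAATAAAGGTCTCCCACTACCCG
GGGTCAATCTCATAGAATTTAACAGTAGTACATCGGCGCGAGCTCACATGCAAACGAGCATTCGACATCCTCACACTTTA
TGTCTGTGCTCTCCAGATCAAGCAGGGCATACTAATTAGACATCGGCGAAACAGGACAACCGAGGGCTAATCTCTAACCC
GCAACTCCGAATGGCTAGGCGAGAAGGAAATCTTGGAATTGGCCTCGACGTTTGCCGCGCATCTTACGGGCGCATGCTGC
ACCGTCGTCTTGCATCTTGACAGACCGAATTTAGCTAGCATCTGGCACTCGGACCGTACGGATCTATTTCAGGGTAAAAC
CTCCCGCTTGGAGGTAGTGAGAGTACAATCGCACTTCACACCAACTGACGTTTAGGTAGCGGCTGACATCCTTTATCGCT
GACGAAGCTGGGCCTTGGGCCTACTCCTCAACCTGGAATAAAGAATGTCGTTGGACTTCGCCTTTAACACTACCGTCTAT
AGGACTCAACCGAATGCGCAACTGGCGCCGCCAGTAGCATCTAGTATTTACGGGATTTACATTCGGATACCATTCGTTAC
CTCTTGGCATCTTTCAAATAATCGGATATT
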
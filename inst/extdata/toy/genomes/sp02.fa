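>sp02_fam1_og1
TTTGGGGATGATTAGCAACGATGGCGCTCTTATCTTCTCGGCAACACAATTTTAGTTGCTACGTTATACGCATGGACTCC
GCACGATGGAGAAGAGGTGGCTTCTGAGGCGTCTGACAGAAGTTTTCGACGTTCGGTCGGGACGGGGTACACCGGATCGT
AAGAATCACAAGTTTGTTCTCGTATGGCAAATGTGCGTCCGTCAGTACCCCAGAATCCAACCACGCCCTTCGACTGAGAC
CACTAGAACCTTTAGGCGATAACATTTAGCAATTTGTGACAATGCCAAGTGTGGTCGATGCTAGGTAACGCCCTTTGCCT
AAATCCCGGCAATCTCTCTAGAACACGGGGCAATCGCAGAAAGGTCCTATATGTGGCCTCCGCGTCTCGGAGTACCCGTA
CGCGGGAGATGCGCCAGTTACAGCTTCGTACTCCAGTTCTTCCGCTTTGGTATTAGTGTCATGAAGTACATTGTTTACGA
CATCTCCTAGGGAGGTTAGGACCCGCGCAAAGTAGTCAAGAACTGCTGTAACTGCAGATTATGGCCATCTCTGTACAGCA
TCGTATCGCTAGTAGCGTGGAATTTTCTTAATAATAAGTCACCAGCTAGGCATATCTGATACGGCTGAGTGTCGTAAAGT
ACGGTTCGAAACAGCGAATTCAATGAGAAGATAGATCTCAAGTGCGATGATCGATTTCAGACTGACGCTTAGGATCAATC
CGCAACGAAACTTTCAATGCCAATTACGTCCTTGATGGAACACGATTGCGTAAGAACCAAGTCCTCCGAAGCGTCATAGG
AACACATCCGACGTCCTACTTTCGCACTGCGTAGCTCACTAGATCCTGGGGACGAGATGTTGGAGGCCTTTAATTGGGCT
TCAATTCTCCTGACGAGCCGAGTGATAACGAGACCGGGAAAGCCGCCAGTCAGAAATTTGGAGCGCGGTCGGATGCAACT
ATACGCCAGCGGGCTTTGTGGCCGCCATTGTTAATCGGAACGTGATGATGTCTTAAGAAAATGTAACTACTGTGGTTGCA
GTAATT
>sp02_fam1_og2
GTGTTTATTTCCGGGCTTTCTTACATTTTAGCCTAAGGTTGATGAGGAATGCTGAAAAAGGATGGTCGAGGGGGGGGACT
CGGAAGAGCATAGTGAGTAAGGAGGTCATGTCGTTAACAGGGCGGATAACCCACAATATATTCAACACTGTCTCTTTCTC
CTATACGCCCCTGCTGACTGGTCCTAGAGGAATGTTTCAAATCAGTTAAGGCGGGCGCGACTTATGACATGCAATCATGT
TCCATAAGCTGTAAGGTCGAGCGAGGTTCTATAGTAAGGAGGCGCTCCCAAACGTGATCAGGGATAATATTTTACTGAAG
TTATCGGCATTGACAGTTTTGTCGCGCTTTGGCTGTCCCCGATCTTGATATGCACGATGCCAAAGTTGGGCGGAGATCAG
ACTAAATTAGCTCATTAAAAAGTGCCACTCTGTGTAACGGTAGGATGCGGTACATAGATGTCCACTAGCACGGGACCTAA
TGCTATAAGCGAAAACAATTGTCCCGCTTATCTAAATCTGACGTTTTGTCGCGTAGCTGCCTGAGGGTCTGATCAACTAG
TCGAAACGGAAAAACTTCACTCAGGATAACTAGAAATACCGGGGTCACATGGGTATAGCATGGGCCGATCGATAGAATTT
CTCTTATAGCCTACCCCATCGTTAACTATGTCTACGGTTGTTATGCTCCACTGTTGTAGGGGCGTGGCTTTAACCATTCA
TCGTGGGCGACCCACCTATATTGTAGACGGCGCGACACATTGCTTAGGTTTTTGACCCCAGGATATTGCATGATCTTATT
AAAGCTATGTTCTCATGCTGTCTCTTCAAATTCTTGCGGATGCTGACTAACAGCTAAAGTTATGTTGACGTGACGACAAA
AGGGCCATCCTGGTCGTGCCCGTAGTCT
>sp02_fam2_og1
CGTTGTAAGAAGAGTGCATCATGCCTCAAGGCAATGAGTGGTATCCGGTTAGGACCATCCTTAGCGTGCCAGACGGAAGG
CACAACACTGCCATGCGGTAGAGGTCATGTAGTTACCTTCATAGGACGCTCCCAATATTGGTACCCGAGCTTGCCTGCGG
AGAACGTAAATCCGTGCCCTCGGCTCCACGAGAAGGGGCAAGAACTATGAGACAATGACTTGTTATATCCTTACAGTAGG
GGAGAGAGCGATGCTCGATGCGCCAGAGTTGAAGAGTTTCGATTAAGAAGCGGGGCTTCGTAACTGCTAGCGGCCTTACT
CTTATACCACCCTCATAAACGTATCCACCTTTCGTAGAAAGAGACTTATGTTGGGAGCCGAGAGCGTAGCTGGTGCGAGA
TGCAGGATGACGTGGCGGGTAGACGATATTCAGTTATCATTAAGTCGTCCCCTTGTCTAGAGTAAGTAAGAAATTATGTC
AGTCGCAAGGCTTAGATGCGTCCGTGACTCAGTAATTGCAGCGACGGCGCAGATATCAAATGCGAGGACGTTGAATGCAG
TTTTGCCTGTTAGGGCAATGACAAGGTGCGTCGCCGTGAGCAACCCACCATTCTAATGTGTCATATTCAAGGTCACTGAG
GCGACCAAGGAGATTTATATTATTGGGGTCCTCATAAGATATGTCCTCACTGGCCAATGTGTGTCTCAGGGGAGGAGAAC
TAAAGGAACCACTCAGGTGGGGC
>sp02_fam2_og2
TCGATGGGGAGGCACATAAATTAGTTTTCTTCGCCGGACACACCTGTGAGCTCTTCGGTGGCCCCGGCTAAATCACGTAT
TTCGTATTGACGAGTAAGGATGCAGGTTACTGACTTCACGCGCGTCCACGCAAGTTTTACACGGCTTAAAACACATTGGC
CAATGCGGGCATATCTTATGTGGCCCCCAGTAATATAGGTAGGCAAAGCTGCACTCGACATCTTCGCATTTTATGTCAGC
AACTCACAATCGCGCGTGCCGATAGGTTTGACCCCACACAGTGCGATGACTTGAGCAAAACTTCGCCCAGCGGTCGACAT
ACCATCATCTTGCATCTGACTTGATGAGAACTCGTGATTTAAGGCTCTCCCACCATACACTTTTGCCGGGAATTTGTAAT
TTCAAGAACCAAGCTCAGAATTAACCTCGCACCAGCTTGGTAGGGCTAGGATTGGTAAAGATGGTATTCATATTGGCGAG
CCCACTTGCAGTAAATGGATGCCTCATTCTTAGGAAACAGTACTCGCAATAATATCATATACGGTACTCCTCTACTGGGT
TTACATTCTTACGACAGTATATCGACGGCGGATGAACGAACATTCTCACTACGTCGGCCACTACAAATCATCACGGAAGT
GTGGTGCACCGGATACCACTCATTCCCTTGAGGCATCTCCCCGCCTCCGACTGAGG
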
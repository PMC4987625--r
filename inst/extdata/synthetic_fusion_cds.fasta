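>synthetic_fusion synthetic 1314 bp carrier-antigen fusion CDS
TGTAATGCGAAAGACTTTCCGGGGATCCACTTCTCAGAACCACCAGGCTCTGTCAGCACG
AGAATGCCAGCAGGACGAGTCGCAGCAGACGGCCGAGGTATGGAACATGAGACCAGCGGC
GCCGTGCATCGTCATTTAGGTTGTCCGACCTGTGCTGGTCGATGCTGGACCTTAGCGTCA
GGCACCCCTCTTATCAACGTACACCCCATCGCCAAATCATCAGCTACCCCGGGTACCGCT
GCGAGGCAAGATATAGCTCGAGTTCGACCGGTCCATGCGCTAATATTGCCCCTACGTGGT
GTTGAAGTACCACTGGCCCAAAGAGCGCCGCAGTCTTATCGCGTTGGGCTCGGCCTTGCG
TTGTCACTAGACAGCAAAGGGTTCCGCATGTTACTACCTGGCGTTTCGAGTGCGCCTTCG
CGTCCCGCTGAACAGCGCGAGGGGAAACTAATCCCCACCCGTTCCGGAGCATTTGTCTAC
AAGCCCGAGACGGTCGAGTCAGGTTACGGATTGTATTGGTCTTACTATTGCGTGCGGACG
GTGCATTGTCCTTCATCGATTCAGGATAACGTTAAAGGTGCGGGATTGTTAATACGCGAC
AACCAGCAAGACAGGCTGGAGGAGGTCCAGGTAAGGATTGCTAGATATCGTTTACCTAGC
ATGTCCGCATGTCTTGCAGCGCTGGCACTAAGTATCTTGGCCTCCATTATGAACAAAAAG
TGGAGAGCCCAACATACAGGACGGGGTCTGTCGACTGATTACGGACTACCAAAATCGCAT
GGCGTCGGCTGTCCTTCGTCGCCCGCCTATATTCTCCTAAACACTATCGATCGCGCTTCG
GCAACTTGGACGTCCGATTACGGCGATTGTAGACGGGGAATGTGTGCCACCAATGAGTTT
GAGATAGGATGTACGCGACTGGTCGCACGTGCGCGTTCCCATCTAGGCTTGGCTAAACGT
ATCCTGAGTCTAATTGGTAGCGACCGCTACGAATTGAATTCGTCGCCCCGACCTGCAGGT
ATGATCGTGCAAGTGCACGAACTTACTTCGTGGGGCGCGACGCGGGGGTATAGACATGAC
GCACTAAGGAACTCCTTCAAGGTGGCCGGAATGCGTTGCACACGTATCGCAGGGGGGCAA
AAACGCGTAGAACAGCGCCCGAATATTTACCGGTGTGCGGCCTTTTCCATTGACCTAGTA
GAGAGCACCTTGGCGTACGAACCGGAAGAGAGGATATGCTATGCATTGCGCCGCGTTGCT
GACAATTGGCGAGCCCAACCTAGAGTAGTCCTCAGAAGGCCCCTTGCTAAGTCA
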
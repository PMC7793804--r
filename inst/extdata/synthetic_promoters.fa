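>synthetic_promoter_A 600 bp synthetic upstream sequence
TATCCAGCCCTCTATTGTACTCCTCGTGCAGCGCCTATGCCACTTCGACTGCGCGGTTAG
GAGCAATAAGATGTGCGTCGGCGCATGGGAGGCGCTGGCCATATTGTATGGAGGTAATCG
TCAGGTCGCGGTTGGAGGTCCGCCACACAACTACTCTTTTAAACGGCTAGACGAGTACGG
ACAGACCACTTTGCGTCACTCGCGGAGTCTAGTCGATCTCAGGCACACAAATCGTACTGT
GGCCTCTTCCCGCGGCCTGTATAGGTAGCTTACGCTTCACCAGACCCTTCCCTCTCTGAT
CCCAGCTAAGATCGTGACAGGACCGAGCACCTATATGGGCACGTCATCAGAGTAATCCAA
CGTGTGCGCGTGCGAGAGGCAGCACATAGAACGTCCGAAGCGTGCATTACGGCGATACGC
TTTTTAGGGCATTGTTCGCCCAACTGGTGGAACAAGCTGTACATCGTAATTATCGACTCA
GCTTGTTACCGATCACTGTAGCCTTCGAAAGGTCCGCCGCACGTCATGGCAAGCCAATCA
CTACCGACTTTCCATTCCGCCCACAGGAAGGGATAGGTTTAAGCGTCGACACCCATAGAC
>synthetic_promoter_B 600 bp synthetic upstream sequence
CGTGTGGCCGTGACCCCCAAGTTCCGTAGCGGATGGAGGAGATGTGACAGAGTGACCTTC
GCGTTACTTATATACTAGCCAATACTGTAGTACGACCGTATGGTGATGGATGCGGTGAAA
CCTATACGTTCTGTAAATCGAATGCGGAAAGCCACACACGGGCAGTGTCCGCCTCACCAA
CCAGGCGAGATTCCGTTCTACGTCCCTTCGTAGAGAGCCAACAATAATATACCTAGTGAT
CCCTAAAGGATTCAAGCGAGCTCAAGAAACATATATCAACCGTATATTTTGCATGGCCAA
TTTATGATGGAGCATTCAACAGCGACCGGATGTGTGACGTCTTCTGTAGTACTAACGGTG
GGTGCGTCCAGCTGTATTCGAGGCGATCGACGGAGATTAGCGTAGATTCATCTCTCTTCC
ATCTAGATTCGTCTGTAGTTGCAATCCTTGCATCAGAAAAAGGTAACACGAATATGCCAA
TTCCTGTGCCTGGGTTGAATCTATCCGGGAACCGAAGCTATGCACGGGACCAGCCTCGTG
CGGTCCGGAAATTTTTGCCTTGCTCGGTGTGACATTTTGACGTTCCCCGTCGCAAACGCC
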
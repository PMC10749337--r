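>SYN-MICA-NM-like synthetic cds_start=86 end_exclusive=1327
TGGTAACACCCAGCTTTGCGAGTACAAATTAACCCGCCCATAGTGACAACATCCGAAATGTAGTATAATG
AACATAAAGTCAGAGATGCGTTTAGTGCTTTGGCAAGGTCGCCCTGGCGAGGAGGGTACTTTAATGCAGC
GGGATCTCCTGCGACTCCGGTGGCGAACTGACCAATCTCATAGCTATCTCCGTATCGAACCATCTTGGAA
TCGGAGGCAATTCATAACTCGTCGTCCCCAGGTAACAATGTATTGCCCCCTGCGCTTAAGTCATAAGGAA
ACTCTTACTAAGTCCATACATGACCAACAACTGGCATATAATACGATCCGCTCGCATGGATATGACACAC
TAGCTGCGCGAGTCTCCGCCCGGAAGGCACGCCAACCGCTACAACCTGACTGGACGGTATCCCAGATACT
TTCATCATTACAGGTCTTGGTATTCCTCGAGGCGAACACGGGAGGTTCTTACGGGGGATTTGCCCACCTT
CACGCGGCGGGTCCAGGTTACGGCTATTGCGGTCAGTGCACATTCTTGCAGGCGCCCAGCTTGGTGTGCC
TCGCTGGAGGCCCACAGCCCGATTCCAGAGCATATATCCATTATGGCCGAACCACACTTAAAACATGTGA
CTGGCTGCGGCAGCTTAATTTAAGCACACAGAGTACGAGGCCGTCAAATCTCAAGCAATGCGGGAAAGTG
CTGTACGGCCCGCATGACCTCGTAGCGACCATGCAGCATTGCTTCATCCGGCTGCAGACTACCGGAAGCA
ACCTATTCCATGAGATACGTTGGAACATACGAGTCGATCAGGGAAGTAAAAGCCGATTTGAGGGCGCCAG
CCCAGACACTTTATACAGGGCGCGAAGTTGGCAGTACAATAGTCGAGTGCGGGGACACAGACGCTACGTC
ACGCGGGCCCCAAACCAAATGGGTATTGACTCAGCAAGTTGTTCCTCGTTACCCAGGACTTCTATTTATG
TCTGGGATATTTATTCTAACGGCGTTTGTACAACAAAGGACAATAGATACCGTTTGAAAAGTGTAGGACA
GTGGGTGTACGGCGCAGTCATTAAAGCAATACAGCCACCGTTTCTGGTACGATCAGTGTTTCAGCGAAGT
GCGTCGTGCGCCCGCTTTGACGAGCAGGAGATGTAGTCGCCATATGTCTCTTGAATAACACAGCTGAGAA
ACTGCAAATCTCTGCAATCGAATGGATTTGTATCGACCTACGCGTGTCCAGATTGCTTTGCATCATTTTT
AAATCTGCCCCCACCGATGTTCGTAGATCGGGCCCACGCCACGGATGAGGTACCACTACTGTTGTCGAAA
CCCTCCCCGCCTTCCAACAACAACACCTAAGCCGTGTCCGTGATCGCTAA
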
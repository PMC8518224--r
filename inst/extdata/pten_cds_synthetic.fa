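>pten_cds_synthetic 403-residue (404-codon incl. terminal stop) synthetic stand-in for the PTEN reference cDNA; codons 124/129/130 = TGT/GGA/CGA, all other codons deterministic filler, NOT the biological sequence
ATGCTTGGATTACCAACCAACTTCGATAGAATATGGTCCTGCAAACGTCAACGGCCGGTG
ATGCCCATTAATTACTTCACAAAGAGCGCGGCACACGCGGATAGCATCTCTCGACTCTGG
CCTGCATGGTTATATGTTTTGTTACTCATATTACACGCTATGTTTAATTGCAAACTTAAG
TCTGGCGGAAATTCGTTAGCATCGACAGCTACTTCACCCTTATGCAAGTGCGCCGCCAGG
TCCCGATGTCTCTCGGTCATTACGCGACCGGCGCGGATTGGTCATACCAGGTTTGTCATT
TTTGAAGCGGAAACCACCCTGGCAAGCCGCATTCATCCGACCTGGGCACACTCCGGCTCA
AGTACAATATGTCGACTCACACAGGGACGACCTACAAAGCCCTGGATGCGATTCCTCGCA
GTCGTTGTCCGCCCCGAGTTGTGCACTCTCCTTCTGCTGAGCCATTCTCAATTCAGCCAG
GGTCGGGGGTTCACTCTCCTGCTATCTATAGCGCAGCAGCAAACGGGGATAGTCAGCCAG
GGGCGAGCAATAGTAAGTTGCGCCAATATGGGAGGGCTAGCTCTGAATAGAAAGTCAGAA
TACCCAAAATTTCTGGACAGCAGTCGCGGCACGATACCGACCAGGTTGCACAACTACCCA
AGTAGGGTTTGGGATGAGGAAAACTGGTGGAGCGACTCTACATGCAAACACGTTACACGA
GGCGAAAACATGACTTTGGTCCCCAGGTCGGGACCACATGCGTTCTGCCTAAAATCAGGG
GTGGCACCATTCTCATCCTGTGACTCAACCCTTCGGCGTACCGCCTTAGAGTCTCTTTAC
CACACGGAGCCTTGGGGGCAGAGAGAGGAAGAGGGTAAAATTGCTCTAGCGAGAACGACT
CCACTACACCCCGGCCTCACTATTGACGGCGATCGGGACAGCGATGCCGCCGCGCCTAGG
GTCCATCTTGATGCAGTTGAGTATTCATGCGAAACTGGTTGTATTCTCACTCCAGTGGTG
CAGCACTGTGCAAAAAGCCCCATACGCTACGTCATGGATAACAACTGCAATCATGTGATA
ACGCCAGGTCGTAGCAGCACTCTTGTGTGTGCCAATTCAGCGACTAGTCAAGATTTCTTG
CGCCGTTTGACCCTTATGGGGGATTCAGTACAGTATAACGAATCTAACCTAGGTCCATCG
GGAAGCTGGTGA
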
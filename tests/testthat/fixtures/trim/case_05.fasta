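>taxon1
AATCGTTTAATGACCA-CGCTGTTA-GTGGACTCGTTTGTTGGAA--CCACCTCACCCGA-GCTTGCG-ATTGTATTTTA
CCGTCGTGCCCTGACATATGCG-GAG-CACCAGATG-TG-AGAAGGCAGTTTTACGCT-GA-TGTAGTCTA-TTG-GGCT
AGATGTCGGCCG-GGGGG-C
>taxon2
AATCG--T-CTGAGCTACGGGGGGC-GACAGC-CGTCTCTTGGGAC-CGACCTCACGAGA--ATCGCGCATCGTCTTTTC
GATTCGTGCCAA-GCACATGTGTGAC-CG-TTGATG-AGCGCCAGTACGTTCTACGCT-GC-CCTAGTCTCTTTG-TGT-
GGTTGATAGCACTTCCGG-T
>taxon3
AATCG-TG-TAGACCA-CGAAGCGG-GACGACTCATTTTTTCGACC-ACTCCTCACTTGATGTAGGCG-ATCGTCTCTTT
CCAACGTCCCCG-TCAGAAGCG-GTC--A-GT-GTGTGACAAGAGGAGGCCCGACGCT-GAAATTAGTCTG-TAG-CG--
TGAGATAG-CGCGTGAGG-C
>taxon4
AATCG-TAATTGACCAACGTGGCTA-GGCAGC-CCTTTTTGAGCC--TGGCCTCACACGAT-GCGGCG-ATGTTCGCTTC
ATTTCGTCCCCAGTCAAACG-G-GCG--A-TGTTAG-CTCAGTAGTCATCTCTACGCT-GC-AATAGTCTATTAG-AG--
A-AAGTGG-CGCCGTTGG--
>taxon5
AATCGATTAAAGACCA-CTACGATT-ATAGCC-CCTTTATTTGAA--CGGCCCCACTAGACGTTTGCG-ACGTTATTTTC
TACTCGTTCCCA-GCATACG-GTGGC--T-GCATTG-AG-AGTAGCTGGTTTAACGCT-G--CATAGTCTCTCGG--AA-
AGAGCTTG-CAATTAGGG-G
>taxon6
AATCGT-A-CGGACCA-CGCGAGAA-GTCGCCTCCTCTATTTGTG--TACCCTCACGTGATGGAGGCGCATATTTGATTC
CTCTCGTACCCG-GCACATGGGTGTCT-TCCTGTTGTTCCAGCAGTCCGGTTGCCGCT-GAAA-TAGTCTC-TCG-GGCT
G-ATCCAG-CCC-GCCGG-G
>taxon7
AATCGC-CAGTGACCAACGCGGTCA-GACATC-CCTCTATTCGGC--CCCCCTTACCGGAA-CGAGCGCATCTTCTATTC
TAGTCGTCCCCC-TGACAAGTG-GCAT-G-AGGGTGTGA-ACCAAGCTGATCGACGCT-GCATGTAGGCTCTTAGGCG--
A-ACGTTG-CATTAATGG-A
>taxon8
AATCGT-G-TCGACCAACGCTGCTA-GGGCTC-CATATCTTAGGA--CCGCCTCACACGAT-AGAGCG-CTGCTGTCTTA
CTCTCGTACCCCGACATAAGCGTGGC--A-AA-CTG-GC-AGCAGTCCGTTTTACGCT-GA-G-TAGTCTT-TGG-CGTT
G-ACGTGGGCGAGCGGGG-C
>taxon9
TATGGCTCATGGACCAACGAAGGAC-GAGGGC-CCGATATTGGGT--AGCCCTCACGCGACGCCAGCGCATCCTTCATTC
TCTTCGTCCCCCGCCACAGG-G-GCG--TCGCAGTG-CC-AACAGTTGGCTCGACGCT-GG-AATAGTCTCTTAG-AGCT
C-AAATTG-CAGGGATTGC-
>taxon10
AATCGCTCACGTACCAACGGGGGTT-GTGGTC-CGTTTTTTAGGT--GCGCCTCACTAAAC-CGCGCG-ATAATACATTA
CCATCGTGCCCGG-CAGAGGGGTGTC--C-ATCCTG-TC-ATGAGAGCGGTGGACGCT-GGAATTAGTCTGTTGGGCGT-
TGAGTAAG-CTTCTACGGCT
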
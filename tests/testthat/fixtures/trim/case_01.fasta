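>taxon1
GTGTAGCAATTTTAGTCCTGAGCGG-GTCCAAGGGCCCTG-AAGGTCG-CCAAGCCCCCCCG--GTAAGTGATCG-C-TG
-T--AAGA-CAGGATAAAA-GACTGTGAGGGGGAAATCCGCTAC-GA-GC-T-TTCATAT
>taxon2
GTGTATTCATCCTGGCGATGAGCGATGTCCGAGGGGCCAG-CTGGAAG-CAATGTGCCCCAG--GCGGAAGAACT-CGTG
TT--GAAT-CATGCC-AA--GACTGTGTGTCTG-CGGT-TTTT--AG--C-T-AACTTTT
>taxon3
GTGTAAGTATTTTACCCCTGATCGT-GTCCAA-GCGCCCG-AA-GACG-TTTGGGCCCCCCG--GCGCGA-AACT-CGTG
TT--TATG-CAAGGC-GAC-GACAGTGAGGTAGGCATGCCATC--GATAC-T-AACATGT
>taxon4
-TGTACCGAAGTTGCC-TTGAGG-G-GTCCAAAGTGCCAG-GGGGACG-ATACGAACCCCCG--GTGGATCATCT-C-TG
TTT-CAGA-CATGCG-AAG-GACTGTGCGATGAGTGTT-TTTG--TT--C-TGAACTTAT
>taxon5
GTGTATCAATCTTGGA-CTGAGCGG-GACCAACGGGCCGGGT--GAAG-CTGTGAACCCCCG--GCGAAAGACCC-CGTG
-T--CAGG-CAAGACAAAA-GACGGTGGGTAGGGGGTCCGGTA-GGA-AC-T-AACATCT
>taxon6
-TGTCACAATGTTCATCGTGAGCGA-ATCCCACGGGCCGG-TGGGAAG-AGGAGCTCCCCCG--GTGATT-AGTGGCGTG
-T--GATT-CACGTGAAA--GGCCGTGCGCCCGTCTTTTAGTT-GGCTAC-T-AACCTCT
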
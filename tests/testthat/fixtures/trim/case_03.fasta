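>taxon1
CGTATCTGCGTTGCC-TCC--CTTTTTTTAATGTCA-ACTCTACGAAC-CC-CGCG--CC-TCTCAAA-TGCCCT-AA-T
CTTATAGGGC--CGGGCCTG-GGGTACTGATAGGTAC-TCGCAG-TAGGATGAGATGACATATAGGGACGTGCT-CAGAT
>taxon2
AGTATCTGGGCTGTC-TCTC-TTT-ATGTTATGCAGCACTCTAATAAC-TC-CGTACCACGCCTACTCATAACCTGCAA-
CTTATCGAGC--CGGGCCTAGTGATAACGGTCG-CGC-CCGCGGTCCGCTTCTT-TG--TTATAA-CACGAAAT-CCG-T
>taxon3
AGTGTCTGTGGTGCC-TCTC-TTT-TTATCATGTTC-AT-CTGCCAAC-CC-GGGCC-CC-TCTTAGC-TACCCT-CA-T
CTTATAGGGCA-CGG-CCCG-TGCTGGCGATCCGAGCAGCGCGG-TAGC-GGAA-TC-CAAATAAGTACGGATT-CAG-T
>taxon4
AGTTTCTGAGGTGGC-TCTGACTT-CTATCATGGTGCAG-CTCTAAACGTC-TGGA-TCCGTCTAAACCTCACCG-CAA-
CCTATAGCGCA-CGGGCCGCGTGCTAAAGCTGTGCCC-CCGCGG-TAGCGGGAG-TTACGCATAATGACGCAAT-AAGAT
>taxon5
TGT-TCTGTGCTGGC-TCGC-TTTTATTTTGTGAGGCAATCTGTCAACGGC-TGGT-TCC-TCTCAACTTCGCC-GTA-T
CTTATAGAGC--CGG-CCGC-TTGTGGCGTTATGTTC-TCGCGG-TTGCGTAAA-TT-CTATTAAAGACGCAGT-CAGAT
>taxon6
CGT-TCT-CGAAGGC-TCGTACTTTCTTTTCTGAATCACTCTGCAAAC-ACTCGGA-CCC-TCTCAACTTTCCCA-CA--
CTTATAGCGC--CGG-CCCT-TGTTGAGGATCG-GTC-CCGCGGTTTGCCTGATATA--CAATAAGCACGAACT-CAGAT
>taxon7
GGTATCT-TGGTGTC-TCAT-TTT-ATTTCATGACGCAGTCTCCTAAC-GC-TGGA-CCCGTTTCACCCTGTCC-GGA-T
CTTATAGTGCA-CGGGCCAA-TGATCC-GCTGCGCTC-CCGCGG-TGGCATCAT-TG-CCGATAAGTACGGACT-CAGAT
>taxon8
GGTTTCT-TGTTGCC-TCGAATTT-GTAGAGTGGGG-AA-CTCTCTAC-AC-AAGCCACCGTCTAAACCTTTCCTGAAA-
CTTATAGAGCATCGG-CCAG-TGCTATTGCCCC-CTC-CCGCGG-TCGCCTAACATGA-CTACAAGCACGTAGT-CAG-T
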
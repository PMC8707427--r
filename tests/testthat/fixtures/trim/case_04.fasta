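>taxon1
TTGG-AAACGCAC-GAAGGTCCTCGGTTGAATTTGCG-TGTT-T-CCTCTCGT-TAGGTAGTAGTAAAACGTATAA-AGG
GAGC-ACCCAACTAAC-ATGCA-C-CTA-CTGACGAGGCACATT-GGAA-TAA-ACGGACCACT-CCATT--AGGACTGC
-G-TGGC-CG
>taxon2
TGGG-TAGCGCAC-AAAAGACAGCAGGTGGGGTTGGA-CGT-GTCG-TATGGT-TAGGAATCAATACAACGAGTTA-ATC
GTGT-TGCAATCAAAC-ATTA-TCCGTA-GTAG-TACGCA-AG--TGAG-TGAATCGCAACGCG-CAATA--CTTGCCG-
-ACTGGATCG
>taxon3
TCGG-A-TCGCAC-TAAGGACCA-TGTTGCTTTTGGC-TGG-CCCTCTTTCCT-TAGGTATCACTACTACGAGTAA-A-T
CGGC-CTCAAT-CGAC-ACGTGTAGATA-CTGGCGTCCCA--C-CGGAG-TTAATCGAAGAACG-CGATTAAGATTCGG-
-ACAGGG-CG
>taxon4
TCGGTT-ACGCAC-CAAGGTGCCTGGTTGAGTATGGC-TGA--C-GCTGTGGT-TGGGGAAGACTAGAACGACTAA-A-A
GACTGAGCAAG--CAC-AC-TATCACTA-ATGG-AAGGCAA-CT-GGAT-TATATCGGAGCACC-CTATT--TCTGCAGC
-G-CGGC--G
>taxon5
ACGGTA-ACGCAC-AAAGGCCTCTAGATGATTTTGTT-TGCT-TCG-TCTCGT-TAGGAATGACTAGAACTACCCA-ACC
ACGC-TGCAAG-AAAG-AGTGC-CCCTA-CTTGCCAGACAA-ATCTCAG-TCCATGGTATCACA-CGATTA-TGTGCTGC
-TC-GGATCA
>taxon6
TAGG-GACCGCAC-CAAGGGCGGATGGTGTTTGTGGCTTGC-AGGT-TGTCGT-CAGGAAGTAATACAACTATTGA-ACG
GAGT-GTCAACCCTAC-ATTT--CATTACATCG-CAGTCATAGT-GTAACTTTATCGTACCACT-CGATTA--CTGCAG-
AA--GGGTCA
>taxon7
TGGG-G-GCGCACGGAAGGCCTAATGGTGTTTTTGTT-TGT-GGTACTTTCGT-TAGGTATTAGTAAAATGAGTGA-GCC
ATGA-TGCAACCTAAA-ATCGA-CCTTACCTCG-GAGACGCAT--ATAACTGG-TTGGAACACG-CTATT--TTTGCAG-
-GCTGGA--C
>taxon8
TCGG-A-TCGCAC-TAAGGTCACATGTTGCTTTTGCGTTGT-AG-A-TCGGGT-TAGGCATTA-TATAACAAATGA-ATC
GAGG-GGCAATC-CCT-ATATG-CCATT-GTCGCAAAACA-ATTCGGAG-TATATAGCCTCACC-CTAAT-ATGTTCCGC
-ACCGGAT-G
>taxon9
TGGG-G-TCGCAC--ACGGCCCGATGATGATTGTGTT-TGG-GATG-TGTGGT-TAGGTATAAGTATAACGAATGT-ACC
GAGCGGTCAAG-TGAC-AAAC--CTATA-GTGGCGATTCACAC--TTACCTGT-TAGTAACACA-CCATTAA-CTGCTGC
AT--GGGT-T
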
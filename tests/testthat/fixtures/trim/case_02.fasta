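>taxon1
AGCAGCGCGGTCCCCG--GT-AGCGGTACC-GGAGC-A-TA-TAGG--TACGGTTA-TAGGGCTGCCTTTATTCCAAATT
-TCACA-TT-A-AC-TTCGAT-TATCGCCCT-T-GCG--T-CGCTT-ATAGGCT-CTGCGTGTTGGCCC-
>taxon2
AGGCAGCGGGCCC-TA--AT-AGTGGAATC-GCAGAT--GT-TGCT--AACTGTTCTTGCCTATGCCTTTA-GCCAAATT
TT-AAC-TG-C-ATATTCGAT-TTACTCTGG-TCATA---ATGCT--TTAGGATACCGAGTATTGGCCAA
>taxon3
AGGAGCACGGCCC-CA--AT-AGCGGGGTA-GCAGT-T-TTTTTGG---ACGGTGATT-TATACGCCTTTACCGCAAGTT
TT-ATC-TA-C-TATTTCAAGATATCTC-GGGG-GAA-A--T-CTT-GTA-GGTACGGCGTATTATCCC-
>taxon4
AGGTAACTGGACC-TT--TGTAGGGTCGCCAGAAGA-T-TA-TAGCG-CACAGTGG-AAGCGGGGCCTTTAGCCCAAGTT
TTCAGA-GA-C-AC-CGCCAT-TATCGCCAG-T-AGG-AT-T-CC--GTAGGTT-CATCGTTTTGACCA-
>taxon5
AGGAGGGGGGGCCCGT--CTTAGAGGAA-C-GCACC-C-TATTAGCG-TACCGTCGTC-GATCAGCCTTTA-TCTAATTT
-T-AAT-ACTC-AACTTCAAT-TATCACTAG-G-TCC-A--T-CTT-CAAAGAT-CCGCGTATTAACCA-
>taxon6
AAGGACCTGGCCC-GC--GATAGGGGTCCC-GCAGC-T-TT-GTGTG-TACAGTAC-GAGCCGAACCTTTATTCAAATTT
-TCAGG-TGTC-AAATTATAT-TATCTC-TG-C-CAC--T-TGCT--TTACAGT-CGGCGTCTTTACCT-
>taxon7
AGGCC-T-GACCC-CCG-TATAGAGGTCTC-CCAGG---TC-TTGCGCTACGGTTATCACGATAGCCTTTAA-CAAACTT
TTCACC-CG-C-ACTTTCCATACATCTGGTG---GGT-ATAT-CT--TTA-GTTACGGCGTTTTGACCA-
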
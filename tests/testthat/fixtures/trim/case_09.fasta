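>taxon1
-GAGC-TCG-GCCGGATTG-CTGC-CCAC-C-GGTCAATGCATGAG-TGCCCTATAT-AAACCTGCTCAAA--TAATGCC
TGTGGGTAG-GGAAC-ATATGATCGATTCCTGCAC-CCGAAT-ATAGATA
>taxon2
-TGAA-TGATGCCGATCTCAGCGC-ACTC-G-GGT-AATGAACGTT-GC-CCTGTATAGC--A-GCGCAAA--A-TAGCT
TGGTGTTTAAGCAA-TCTATTATCGCGGCCG-CAG-TCGTAC-AGATCTC
>taxon3
CCCGC-TTT-GC-CACGTA-C-GC-GCA-GG-GG--GGTATAAGAG-TA-CCTATATAGGA-GTGGACAAA--GATTACT
TGATGCTTC-GACC-TATTTCAACTTTTCCGGCACGGCGTAG-CAA-CTT
>taxon4
CACGC-TAC-GC-AACCTG-ATGC-TCA--G-GGA-ACTAAAAGCATAC-CCTATATCGC-CGGGCAGAAAC-T-TATAG
TGAGGATAG-GCTAC-ATATTATCGAGCACG-CAGGGCGTAG-CAATATT
>taxon5
-TAGC-TAG-GCCCCCCTC-ACGC-GCAC-G-TGC-AATTTATGTA-TC-CCTATATCTA--CCGCTCAGG-GG-T-TCG
TGGTGATGG-GACAC-GTATCATCGC-ATCT-CACGGCGTAGGAAATATC
>taxon6
-AGCC-TCG-GCCCTCTTC-TTGC-GCAC-G-GCT-ATTAAATGCTTCG-CCTATTTGAT-CCAGCCCAAA--T-TTTCC
TGGCGATGGAGCGT-TATGTTATCCCTACCTGCACGTCGTAT-AAAAATT
>taxon7
-AGCC-TTA-GCGTTAGTG-G-GCGACA--G-GGG-ATTACAGGCG-CACCCTACATCGG-CTAACCCAAAC-AATCCCC
TGGTGATATAGAGGCTTTCAAATCAGAATCCGCAA-AGGTAT-CCA-TT-
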
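>taxon1
C-GGTC-CAGCTAC-GTTG-TGTTACACAGGAAGGGTGAGACTGCTTCCCCACCATGCACTTTTTCACACTT-GAGCACA
ATAGAAGGAAATGATGG-GCC-ATAGCCCTGGGTTTGAC-TTCGAATCTCT-AACCCA-C
>taxon2
TTGGTC-TAGCCAC-GGTT-TG-GCCCCCGCAGTGGACCTTCTGCTCTCACGACATG-TCAC-TGTCAACGG-GAGAACA
ATCGTAGGAGTGGATCG-TCC-ATAGCCCC-GCTTCG-G-AG-TACTCTGT-GACCCATA
>taxon3
T-GGTC-TAGCTAT-GATG-TG-GACACGGT--TGTAGAAACCGCGGTCACCGCATG-TCCT-T-CG-ACAT-GAGCAGA
ATTGTAGGAGAGA-AGT-ACC-CAAGCCCAGGTTTCGAA-AG-TATTCTGTTTACTCA-T
>taxon4
T-GGTC-TAGC-AC-GGTT-TG-AGCACAGTA-GGTAGGCACTGCTCTCACTTCATG--ACC-T-CT-AATT-GAAAACG
ATAGTAGGAACGG-TAT-GCGAATAGCCCCGGCTTTG-G-GGCCACTCTCTTGACCCATT
>taxon5
T-GGTCCTAGC-AG-GTTA-TGTCACAATGA-TCGTTGAGTCTGCTATCGCTTCATG-TCGC-TGCCAACAT-G-CAGCA
ATCGTGGGATGCT-TTC-TCC-ACAGCCCTGGCTTCGAGCAGCTAATCTCTTAACCCATA
>taxon6
A-GCTC-TACCTAG-GCTT-TGTAACATTGCAAAGTGGCACCTGCTGTCACCCCATG-CCTT-TGGACTCGT-G-GCACC
ATGGTAGGAGTTTATTTATGCAACAGCGCC-GCTTGG-C-GGCGATTCCGTTTACCCATC
>taxon7
C-GGTC-TTGCCAC-GCTT-TGTTGCAAAGA-TAGCTGATACTGCTTTCGCGACATGCGCTGTTCTCAACTTTGACGACC
ATAGTAGGAGGCAATCC-GCC-ATAGCCCAGGTTTAGAG-CG-AAGTCTCTTGACCCA-C
>taxon8
C-GGTC-TAGCAAT-GTTA-TGTACCATCGT-TTGTCGCATCTTCTCTCTCTGCATG-CCTA-TCAATAC-T-G-CCACT
ATTGTAGGACAAT-TAG-GCCAAAAGCCCT-GTTCAGAC-AGCCCATCTGT-CACCCATG
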
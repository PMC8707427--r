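>taxon1
GGATATGATAA-TACTGTCT-TACTGTTGTTAAGCATTTTCAAACCTTCTAAACCCAGTAT-CGT-GTCAT-ATAGATA-
GGTCTACGATATCGA-A-CCATT-A-CTGAGACCAGCTAC
>taxon2
T-TGCTGCTTT-TACTACCT-TAC-GACATTACATA-TTTAAACTCTTCT-A-ACAAGAA-TCGCTGCCATCATT-CTA-
GGTCTCCTACATCGA-T-CCATC-TCTTGTGTAGATTGAC
>taxon3
C-GGGTGGTCA-TACTTCCC-AAC-GTTAATACTCA-TTCTCAACCTTCT-AAGCACGAATACGA-GGCATCATACCTA-
GGCCTTCCATATCAA-C-CCAT-GGCATCATATTA-GTAC
>taxon4
TTCGGTGTTCA-TAC-CCCT-TACTGCGGTTA-TAA-TTTAGATCCTTCT-TAACACGAA-TCGATGTCAT-ATAACTA-
CGCCTACTGAATCAATG-CCCTAGA-TTGGCTTAACTTAC
>taxon5
TCGAGTGGTTG-TGC-TCCT-GAC-GTGTTTA-CGA-GTT-TATCCTTCTAG-ACGGGCAT-GGACGAAAT-ATCACTA-
GGGATCCCACATCAA-G-CCGGTGCCGTCCAGTGACGCAC
>taxon6
TGTGTTGTTAT-TATTCCCT-GACTGCAGTTATAAA-TTC-GAATCTTCTAA-CGCTGGA-ACGGTGCCATCAAT-CACC
GGACTGCGAAATCTATG-CCGGA-CCTTATCTTAA-TTAA
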
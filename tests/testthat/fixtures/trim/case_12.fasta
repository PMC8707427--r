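>taxon1
AA-GGAGGGAT--GTT-CTATCTCA-CT-GGTCAAGGAGAC-CGACGAAACTGACGCAT-CAGACCGACCGTGACAGCGG
ACAGC-GTCATTGCCATGGGTTG-C-GGCCAGCTC-G-GTCCCCGT-C-AATT-GATAGTGTGTCCCG-C--GCACTAGG
>taxon2
AC-GC-GATTA--GGA-G-AGCTTA-CT-GGTCCCGGAGCA-TCAGGACCCTCACGTAA-CA-GGTAACCG-GACTTC-G
ACAGG-ATC--CGCCTTCGGTTG-G-AGCCTACT--GGTCTCTCAT-A-AAATGGGAA-GGGGCACCG-GGCAGTTTCAG
>taxon3
AA-GC-GTACA-CTTA-CCACCTCATCT-CGTCCTGGAGCA-GAATGAGACGTACGTAG-CAACGCCAACA-GTCCACGG
CTAGT-GTAATGGCTATCGGTTT-A-CGACTGCTTGG-GGTCCCTG-CTAAAG-GAAAGTGCTCATCG-GG-CATTTAGG
>taxon4
AG-GC-GGCAG--CCA-AGATCTAATCT-TGTCGAGGAGCT-AGACGAT-CTTACGACG-CA-TACTACCT-GGCAGCAG
GTCGAAGTC-TCGTGATCCGTTG-T-CGACAACTT-GGCAACCCAC-G-AACC-ACAA-GGGGAAGCG-AC-GAGTTCAG
>taxon5
AG-GT-GCGTAT-CCA-CCATCTTA-CT-TGTCACGGAGCG-TCAGGATGCTGACGATC-CATCACAACCT-AACGTT-G
CACGT-ATTA-TGGGAGTTGTTACG-TGTCTACTG-G-A-ACGCAC-G-AAGAGCTAAGCGTGAATCG-GGCAATATGCG
>taxon6
AT-GCAGGGCT--ATA-ACACTTGATCC-CATACTGGGGCT-AAATGAT-CTTACGAAT-CAAATTGACCA-AACACATG
CGGGT-CTT--CGCCATATGTTT-G-TGCCACCT--AGCGCCACCG-T-AAGA-TCGAGCGAGTACCGATCCTAAGTGAG
>taxon7
AT-GG-GTCGTT-CTA-CCAACTGATCT-CGTCAGGGAGCT-AGAAGAAGCTGACGTGT-CACGGTTACTA-CTCTTA-G
CTTGCACTG-TTGCAATACGTTA-AGCGTCCCCTGGGGCAGCTTCG-TTAAGT-AAAAGGGGGGATCG-C-CATGATCTG
>taxon8
AT-GCAGTAAG-CCCA-CCAGCTTA-CG-GGTCCCGGAGCT-CGAGGAGGCTTACGAAT-CATCGGCACCAT-ACGGTCG
GGTGTACTCATAGGTATTGGTTT-C-AGTCTTCTT-G-GTTCACCA-A-AAAT-CTCAGCCCGGATCG-AGCGGTCTAAG
>taxon9
AG-GTAGATAA--GTA-GCAGCTCATCC-AGTCTGGGACCTTGGATGAA-CTGACGTCT-CA-TGTTACCC-AACCCGAG
CCCGC-TTGA-TGGCATAGGTTT-T-CGGCGTCTTGGGTCTCACTG-A-AAGT-GGCA-AGGGGAACG-TGCCTGCTGTG
>taxon10
AGAGAAGAGTCTCTTA-GTATCTTA-CT-GGTCTTGGAGCG-GCAAGATGCTAACGGCA-CAAAAACACCATGTCGTTCG
ATAGGACTT--TGATATAGGTTT-GGTACCGCCTC-G-C-ACGCTT-GTACAC-AGGA-CGTGCATCG-CC-CAGCTTTG
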
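>taxon1
--CGCAAAAGGGAT-TTCACGC-TACG--CGTAAGCTTTGC-TTTTAT-ACCC-GTTA--TATTAAAA-T-A-CC-GCTT
TATAGAACT-ATTAGTCGAATAAGT-AA-CCTCGG-A-TAATGCG-CTAA-TCTTAAAACACATT-ACTG
>taxon2
-ACGCAATAGCTATCTTTGTGCACACG--CAATAACAC-GA-TTCTATAAATC-GTTA---ATGTACCCA-A-CC-CCCG
-ACCGGACT-ATTGGC-AC-TGTTTTACATCCCAGAAATTACCCG-ATCA-GCTGAAAACAAGTTACCTT
>taxon3
T-CGCAGGAGCCAT-TTCGAGCATAAG--CAAAATCAC-AG-CCCTAAAAATT-GCTA-T-ATGCACG-A-G-CC-TCGG
-ACTGCACT-ATTCGT-GA-TGGAC-AGAACACTG-A-TGTTCCG-GTGA-ACTCAAACCATATTGA--A
>taxon4
--CGCAAAAGTTATCTTTTCGCACACGA-CTGAAGCCCTAG-TTATAT-AATCGGTTA---ATCAATTCC-A-CC-GC-A
TACGAAACTAATTTGT-CA-TGTTG-AGGACTCGGAA-TGGAGAC-GTTA-ACTCAAA-CAGATTCG--T
>taxon5
--CCCACTAGAGAT-TTCAAGC-CACG--CTGAATACTG-G-ATGTATAAAACGGTTA--TATTAAGC-CCA-CC-GCAC
-ACGGGACT-ATTAGTCCA-TGCAGTAGACCACAG-A-TTATGTG-GTAACGCTAAAATCATATTCC-TG
>taxon6
T-CTCAATAG-GTT-TTCTGGCTTACGA-CCAAACCCAGGT-GTTTATAAATCGGTTA---ATTGAT-CG-A-CC-AC-T
-ATAG-ACT-ATCCGT-CCATGAAG-AGCGCGCCG-AATGGAGCGAATTA-CCTAGAA-CAAATTAGCTC
>taxon7
-ACACAGCAACTAT-TGGTGGCGCACGATCAAAATCTCTGC-CT-TAT-AAAC-GTTA---ATTAAGA-CCA-CC-TCCG
TATCG-ACT-ATTGCT-AGATGTC-TAAAGCAAAG-AATGGTTCGAATCACACTGAAATCAGATTTACTA
>taxon8
-ACCCAAAAGATATCTTCGGGCCAACG--CTTTATCTGGCT-GTTTAT-AAAC-CTTA---ATCGAGACC-A-CC-GC-A
-AGAGCACT-ATTCGT-ATATGCTT-AAAGCACAGAAATGCATCGACTAACACTTAAACCACATTAA-TG
>taxon9
--CCCAAGAGTTATCTTGGGGC-AACGA-CCTGAACCCA-T-CTTTATAAA-CGGTTA---TTTAACA-G-ATCC-TCTT
-ACTGTACT-ATTTGT-CAATGTCCTAG-GCGCCG-A-TATAACG-ATAG-CCTCAAAGCAGATTAAC-A
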
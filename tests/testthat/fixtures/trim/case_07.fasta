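>taxon1
GGGTG-GC-T-ATGTATACCGAACTAGGTCTTATA-TAGAGGATGATA--GAAGGAGCATTAAAGTTGGGTAGTCCT-CG
ACAGCG-TACAT--GAAAC-GCAGTA-AG-GCCCTCGAAACTTA-GA-AGGGGGCAGGTATTGATG-ACGCTTCGA-AGT
AGGCCAT-CATT-ATCGGATC-AGTTTGGTCGTCCGCGGG
>taxon2
AGGAGTAC-GAATGG-AACAGATCTATGTGTTA-ACCAGAGCGAGCTTAGGGAGGAGGATTGACGTTTGACAGTCAT-CA
ACAGTGCGACGG-AGGAGT-GCATATAAGCGGTATCGAAACTTA-AA-AGGAGTATGATGTTCACAAACTATACGGGAGC
AGTGCGATGTTG-TTCCG-TA-C-TTTCTACCTCTCAGGG
>taxon3
AGGCG-ACGGTATGG--GCAGAACTATGTATTC-ACTCGAGCC-TATTT-AGGGGAGTCTTCAGGGTCGGCAGTCGTGCA
ACAGCGCGAAAC--GGATCGGCAAGGCAG-GGCCTTGAAACTTAAGG-AGGAGATTTGTCTTGATCAAAC-TTCGA-A-G
AGGCCGATTGTT-CTCCGAGA-ATTTTTAACTTCCGAGGC
>taxon4
GGGCG-TCGGTATGT-CACAGACCTATGTGTTGTA-GTGAGGGCTGTCT-ACAGGAGCATTGAAGGTAGGAAGTC-TGCA
ACAGCGC-AAGCC-GCAAGGGCACTTGAG-GGCCTGGAAACTTAATC-AGAGGTTCGTTCTTAACGAAGTATTCGT-AAT
AGGCCATTTTTT-TTTCGAGT-AGATTGCTCATCTGTGGA
>taxon5
GGGGG-AC-GAATTG-GCCAGAGCTACGTTTT--A-GTGAGGA-CCGTG-CGTGGAGGGTTGACGGTTGGAAGTCTTGCA
AAAGCG-CAATA--GGAGC-GCAATTGAG-GGCCTCGAAACTTAATG-ACGTGCCGCCTCTTTAGC-ACGTCTCGT-AAT
AGGCCATT-GTT-CTACG-GT-ATTTTGTTCGTCAGCGGA
>taxon6
GGGAG-AC-GGATAC-GGCGGATCTACGTATTGTA-CAGAGACGTTTTA-AGAGGAGGTTTTATGCTTGGTAGTC-TGCG
ACAGCA-AATTA--GCAC-GGCATGGAAG-GGCCTCGAAACTTA-AT-AGGAGGTCGTTATTGCTC-AGCATTCGA-ATT
AGGACCC-ATTA-GTACG-AC--GTTTTCGCTTCGAAGGA
>taxon7
TGGGG-GCGG-ATGG-ACCGGATCTAGGTATTCTACAAGAGGACGATTA-AGCGGAGAATTCAAGCTTGACAGTGAT-CC
ACAGCGC-ATAC--GGAC-GGCAGGCTAG-GGCCTGGAAAATTAATGCTGGAGCAGTGTTTTAAGAAATGATCCGG-AAC
AGGCCAT-A-TG-GAACG-TAATGTTTCCACTTCTGCGAG
>taxon8
TGGAG-AC-GGAGGC-CGCCGACCAACATGTTTTACTCGGGACAGGTA--GTTGTAGATTTAACGCTGTGTAGTCGT-AC
ACAGCG-TAGTC--GAAC--GCACATCAG-GGCCTGGAAACTTAACG-AGGCGGGCTAATTCCATC-ATC-TACGT-ATT
AGGTTGG--ATC-CTTCGAAT-C-TCTCGGCGTCAGCGGA
>taxon9
GGGCGTTC-GTATAC-AGCAGATCTAGGTCTTATA-GTGAGATATGTG--AGTGGAGGCTTTAGGATGGCGAGTCGTGCA
ACAGCG-TAGGA--GCATA-GCAAGTAAG-GGCCTTGAAACTTA-TC-AGGAGACTTGTGTTGACCAATGTTGCGC-GCT
AGG-CTA-G-CT-ATTCGACCATGTTTGTTCATCGGGGTC
>taxon10
GGGAG-CCGG-ATAC-GGCGGAGCTGTGTTTT-TA-GGGAGATCTTTTG-AGAGGAGTCTTAAAGGTAGTAAGTCATGCA
ACAGCGC-ACCTC-GGAGA-GCACAGCCG-GGCCTAGAAACTTAAGA-AGGTGTAGATTATTTAGC-AGTTTGCGG-AGA
AGGACTA-GGTC-ATACG-GT--TTTTTCCCGTCCAGGAT
>taxon11
TGGAG-CC-GGATAA-GGCTGACCTACGTATT--A-AAGAGGCCTCTAA-GATCGAGTGTTCACGATCGTGAGTCCTGCA
ACAGCG-CAAAG--GAAAAGGGACAGGAG-GGCCTTCAAACTTA-CT-AGGAGCTTTCTCTTGATAAAAC-TGCGG-ACG
AGG-CCGTGGTCCGTACG-CAAC-TTTGATCATCTCTGTA
>taxon12
GGGAGTAC-GAATCG-GACTGAACTAAGTATT-TA-TCGAGCA-GTTG--CGTGGAGCATTTATGTTAGGAAGTCGTGCG
ACAGCGCAAACT--GTATC-GCAAATCAG-GGCCTGGAAACTTAACT-AGGGGCAGCTTTTTAAGTAATCATGCGAGATA
AGGACTATTGTG-TTGCG-CGAAGTTTGTCCCTCTTGGGA
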
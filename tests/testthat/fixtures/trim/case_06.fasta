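>taxon1
G-CTGAG-AA-CTAAGGAAATT-CT-CGTTCTCG-G-G-G-CGGCCCTCTATCGTCGCAGA-TGTTACAC-TTCCGTCC-
GTA-ATAAC-TGAA-TAGCA-GGCG-ACACTCGCCG-GG-GT-CGAG-ATTCGT--GCG-G-TAGTGTCC-GTGCTACAC
C-GAGAGCTCATTATGAGT--CACAACCTT
>taxon2
A-CTGGG-CG-CAACCAAAAGT-CT-TGTAT-GCTTCG-G-AGACGCTCTTGAGC-GAAGACTAGACAAC-TTCTGTCAC
GAA-TTGGC-TGAA-TAGCA-CGGA-TCACCCGCCG-GC-GGGCGAGAATTAGG--ACGGGAGAAGAGTG-ATGCTACAC
C-GAGACTTC-ATGTG-CTA-CTCAACACC
>taxon3
A-CTTGG-TTCCAAACCAGACTCCT-AGT-C-GGTCGG-G-GGACACTCTATGGA-ATAGA-TGCTGCAC-TTCCGTCTC
GTG-CTGA--TGAA-TTCCAGGTAT-GCACTCGGCG-GT-GTGCCGG-ATTGGG-TTCGGG-TAAGGACG-ATTCCACAC
C-GAGTGGTCACTATG-CT--CCCAACTCC
>taxon4
A-CTAGG-GG-GGACAGATACTCCT-CGTTG-GC-GGG---TCCCTC-CTGCTGC-TAAGACTTCTTAACGATCCTTCAC
GTTAATGA-ATGAA-TCCCAGCGCG-CCACGCGCCG-GCATCGCGTGAATTAGA-TTCG-G-TATAGTGT-TTTCAACAC
C-GAGAGTT--ATATGACT--CGCAACGCT
>taxon5
AGCTGGG-GG-TTAGCCATAGT-CT-CGTGG-GATACG---TTTCCC-CTCGAGG-GTAGA-TCACTTACGGCCCGTCTC
GTAATTGGC-TGAA-TAATA-CGGT-AGACGCGTCG-GC-GC-CAGG-ATTCGG-TCCG-G-TAGTGTAC-CTTCTACAC
C-CAGAGAT--GTTTG-CT--CCCAACTAT
>taxon6
AGCTCGG-CA-CAAGTCAAATTCCT-GGTAC-GCTATG-G-CCACTA-CTTTCGC-AGAGACTCCACTACGACCCGTCG-
CTG-TTGCCATGAA-TGCAA-GGCA-CCAGTCGCCGGGA-GA-CATGAATTAGG-TGCGGG-TAACG-CGTATGCAACAC
C-GAGTGTTC-GTCTG-CT--CGCAACACA
>taxon7
A-CTTGGTCA-GTCCGGAGAGT-CT-TGTAT-GT-C-G---GACCAC-CTGCCGCCGTAGA-TACTGTACGTCCCGGCT-
GTCAATGG--TGAA-TGGTG-AGTC-ACACTCGCCG-GA-GAGCCTG-ATTAGC--ACG-G-TAACGA-A-GTTCAACAG
C-GAGGGTTCATTTTGATT--CGCAACGC-
>taxon8
A-CTTGG-GG-GGACGGAGATTCCT-CGTTG-GGTAGG-G-TC-CACTCTGCAGA-TTAGA-TGCGCGACGAACCGTCGC
GTTACTGTC-TGAA-TACGAGTGTC-ACACACGACG-GG-GTGCGCG-ATTCGC-TATG-G-TACTGGAG-TTACAATAC
C-GAGGGGT-AGTCTG-GT--CTCAACGGC
>taxon9
A-CTCGG-AT-CGAGGGAAAATCCT-GGTCA-GA-TAG---GATCAC-CGTAAGC-CAAAACTTGAGCGCGGTCCGTCC-
GTT-TTGTCATGAA-TGATAGTGAG-TCACACGACGGGT-GCGCGCG-ATTAGT--CCGGG-TGTGGTGT-ATGCAACAC
C-GAGCGCTCA-TGTGAATA-CAGAACTCA
>taxon10
A-CTGGG-CA-GTAGGGAGAGT-CG-AGT-C-GTTGGG---ATGCGCTCTGTTGA-ACAGA-TAGCCCACGAACCGTC-C
GTT-CTGC--TGAA-TTTCAGGGCC-TCACACGTCG-GT-GGGCCCGAATTGGT-TGCGGG-TACGGACA-CTTCAACAC
C-GAGAGCT-ATTCTGAATATCCCAACGCT
>taxon11
AGGTGGG-TC-GGAT-CACACTCCT-CGTCATGC-G-G---GTGCTCTCTGAAGCCTCAGA-TCAGCAAC-GACCGTCAC
GTAAGTGAC-TGAA-TTCAA-GGCA-CCACCGGGCG-GT-GG-GTTA-ATTGGT-TCCG-G-TAAAG-TA-ATACTACAC
C-GAGTGATC-TTTTGAAT--CGCAACGTC
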
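>HBB_GFP_amplicon synthetic 6-kb allele-resolved editing fixture
ATCCCTTCGTGGTCAGATTTTTGCAGCTTTGGATCTCCCGTTTGCACGAATGCCGTGCAAGAAGGGTCCTTCGAACTAGC
ACATCCATAACACGACACACACGGCCGCGTCGCGCGGATGAGGGTCGATACCCCGCGATCTAATCACCTGGTGCCAGTTT
GTCCGGAGTAATTGTAGCGCTTCGGCTACTTGTAACTCATGAGTTAGGCAATGCAGCCCAGGGAGCAGCAGCTCATCAGA
CGTCCGATCACAGCGTAGGCTTTCAGGTCGTAGTATCATCCATATACCTCGAATTATAGCGCTCTATAGTGCGCTTTCCT
AGTCCCCGAAAAGGTGCACGGTATGCAATCACTCATATGAATCGTTTGGCTTCTTGACCGGGGCTATCTCAGGCCTAAAA
AGTGGTGTCGTGACCTAGGGCGGTACCTGAATTTCCATCGTAAAACGACCTACTCGACGATGGACCGCTGGTTTTTGGAA
CGCCGCTCACGATAGCCACGCCTACAATATCCAAATCTAGACAGCGTAGACTAACTATTATCGCGATACTGTCCCGATTA
AATTGACGACATTGCTTCTGTTTTCAAGCTGCTAGGACAGATGGTGCATCTGACTCCTGTGGAGAAGTCTGCCGTTACTG
CCCTGTGGGGCAAGGTGAACGTGGATGAAGTTGGTGGTGAGGCCCTGGGCAGACTTAGCGTGCGGACGGTACTGTTGAGA
CGACGCATTGTCATAGTTGTTGTAGAACCATCCTCACATTGCTGAATATCACCTGCTGGTAACTATAACAAATATGATGC
CGCGCTAGCAGACCCTGTTCGAGCTGCTGGTGGTCTACCCTTGGACCCAGAGGTTCTTTGAGTCCTTTGGGGATCTGTCC
ACTCCTGATGCTGTTATGGGCAACCCTAAGGTGAAGGCTCATGGCAAGAAAGTGCTCGGTGCCTTTAGTGATGGCCTGGC
TCACCTGGACAACCTCAAGGGCACCTTTGCCACACTGAGTGAGCTGCACTGTGACAAGCTGCACGTGGATCCTGAGAACT
TCAGGAAAGAGATCATAAATTAGACGTTTTGCGAATGGTTTCGGGGTAAGCAGAGTGCATAGCTGTAATTCTTCGTTTAA
CTCCCAGCGCACCTAATGGCATTTCTACACTGGCCCGCTCCAAGGTAGTAGGTTCCACACTGCAATTACGACGCTTATAC
TGAAAGCGAGGATTTGAGGGATTGTATCATCTGCTGAGCGGCTTCTTTATATTCAACCCTTCCGGAATGAGCTTTTGCGG
TGATTACCTGAGAAATAAGGGTCGTCTTCGGTCGGATACCAGACTATTAGCCGAGGAGCCGGAGAGCGGGTCCCTCTAAA
AAGTCGTGTAATCCGAGGTGAATGTACAGCGTTCCATGTTGGGGCAACTTCCCCGTTCCCGTGGCTGCTTTGTCTTCGCT
GCATACTACCGTGGCAGCCGGCCTCAGATCGTGTGCTATAAACAGTGACCTCCCGAGGTGGACCCGATAACTTCTTTTAG
CTGTCCTCAGTAGTATGCCTATAGCCGGATGGAAACTGACAAAGCGCTTAAACCGGCCTACGGCTACTATCCCCGAGATG
GTAGCTCTTTGCAACTAGTACGACATATGGAAGCACGTAAGAGCGGTGCCCATCTAGTTAGGCTTGCTGTGAGGTTAAGG
ATGCGACAGCTAGTGCTCTTTCTCTTATATAAATGGTCAGTGAAGTGATTCCGCAACGCTCCCGCCGGAGGTATGTATGT
CACCTTGTTTCCATTACGGGTAAGCCCCTGGGAGCTTGGTTTCCACATATGAGAGCCTGAAACTAGACCGTATTCCCACA
CCCGCCTACTCATGACACAGCTAAACATTAGGCTTTGTTTTAAGGCGGTCGCTATCTCCTGGGCAACGTGCTGGTCTGTG
TGCTGGCCCATCACTTTGGCAAAGAATTCACCCCACCAGTGCAGGCTGCCTATCAGAAAGTGGTGGCTGGTGTGGCTAAT
GCCCTGGCCCACAAGTATCACTAATAGCTCAAAAGACGCGCGTAGATTCCGGCCTCGGTGTTTGGGCAAACCGTCTGAAC
GGAGAAGGTCCGAACCACCCCGTCTCGTTAACTCTGCAATTTGACCAAGCGGCATCTTCGGGTCCGGGCTTTATCCGATA
GGTCCAATAATGTCTCCGATTTAGAGGTCAAAGAATGTTGGATCTATAGCTATTCAATAATTAAGGAAATCATTTCTTCG
AAGAATAATGGAGGGCTTGAATCGCGGATTGGGTAGATGCTTCTACCCGTGATACCCATGGCTACATCTGGTGCTGCACC
TTCAACACTAGAACGGCTATGTGACGACCTAGCATCTAATCTTTCAGCCCCTATTAAATAGACACGCCTCGGCACAAGGA
CTCACTTATGATTCTTCCTAGACATGGCAATAACGACCCACGTGTAATTTCCACCCACTCTATTTCAAGCAAGATACACC
CCGTGGCCCTTCCACCGCTATTAGCCCTTCGCTTAGCTGGCTTGGTTCAAACATATGGCCTATGTAAAGAATAACCATTC
ACCTGGCAGTGGTATGTGTAATATCTTCCCCTTATGACACCTATGCTAATCTTGACGCTACACTATTGATCTTTCTCAGG
ACTTTTCGTTTCGCGAGGAGTACCCGGCCTCCGAAATGTTAACAACACTGCTTATGGCAGTATTGACACGAATTAGCACC
TTATGCCGCGTTCCAAGCGACCAAGGCTTGGTTTGTATACGCTGCGAAAATTACGTACTCTCCCACGATCCCGCAGGCTT
CCGTTATGATACGCGTAATATGAGTTTAATAAGCCACCACCATTGAGCGTCCGGCTGATGACACCTTATTCCTTAACGGG
ACTGGACCAACGGGACGCGTAAATCTTCCGCCAACCGAGACTGAACATCCACGGTGCGGGCATCTTCTGATGCGGTAAAT
CTATTTACCTTCGAGGACATGTTTACTCATACTTGGACCGTGGCCATGCAGCGCTAGTAGCACATTGCGAAGAATAGGAA
GCTAGCCGTCGACCTCATTAACGCTATAAACGATGGCCTCTGGACAATCGACCGGGCGACCCCTTGAAAGTACGCCGGAA
GTGGTTGAGTCTCAGCGGCTACGCCTTCATGGAGACAAACTAGAAAACCTTAGTTCGAATGCAGTATTCCCATACTCCTC
CTTTGCAATACTTCCTTATTGCAGTCTGAGCACTACGCCCCATCATGACGGTTGCATCTGCGCCTAAAAGTGGGGACCTA
CTATTTATTGTTCCATCCGAGTCTAACGCGGGCGGAAAGCCAAGCAGCCTTGACTAGTAGGTCGATGGGGCTCAGCTTCT
TAGGATAAAAACACATACTGGTTCTAATTGTACGCGGCAGCGTTCAGGCGGTAGTCTGGAATCCCTTCCCGACCACGCAT
ATGAAGATGGAGCGTCGTCCAAATTATAATGCTCATAACCTGGCCGGTCTGGCGAGGAGCGGCTGATTCTCGCCAGCATG
GTCCGTGTGTACGTCTTACCGCTCACTCGTTGAGTCCACTAGAGTTAACACAATTCAAACATTCTGATATCAGCTTTTAA
CCTTGGACAGCTAATGCGTGTCAATAGCGGGAAAGTCGAGGTTCGGCCCCCTTAAGTGTGGGAGAGAGCCGCAGGTACAC
TTCAATACGGCACTCGTCAACACATCATACTGATACAACCACGGTAGACTACAGTTCGGTATCCATTCAATTCCTCCCAA
CGCCCGCCGTGTCCTAAACTCCATGCCCGAAGCGGGCCTCTTGTTACCCTGCTGGGAACTCTAAAATGGGACCAGGTGAT
CACTACCCTTCGAAGTGTCCATCGTAGAACGGTTCGCCATTCTCTGAATAAACTCTTCTGTCGTGTTTGGGCAGTGCCAC
CTAGCCATTAGCAACTGCTCGTAGCGGAAAGCTCATACGAATCTCTTCCGGACGACACGGTGGACATCAGATACTTCGGA
AAGGAGAACAACTGAAGCCGTCCAATTACCTCCTAAGTCAAAGCTTCCCCCTTATATACAAGGAACGCTAAAAGTTCGGG
ACGATAGACTGACGGTCTTGGTAGAATTGAAGCTGTGGATCGATTGACGCACACACCCAAATAGTACCTAACCCGGGCTT
TCGTGCGATACTTGTCCTTGTGGGTTTAACGGCGTTAACTCGGAGTATGCGCGAGCGGGAGTCTAAGATACTTCTAAGTG
ATGCCGTCCGGCAACATGTCGGATTAAGGTCCATGACAATTCGTATTATGCCTGCGGCAACTCCGCTAACTATCTTACAT
GCAATTCAACTCTGTGGTTATGAAGAGGAGTTGAACGAGCAATAAAGTTTAAGACCCTCCGTTCGGGACATCGCCCCGGG
CTGGGAGGTTAATTACCCCTGTTAACCGGTTACTGTAGGCACTCATAGAAAGGGCCGAATTCTCTCACCCTAAATATGTT
GTATAGCCGGCACACTGTTCCCGAACAACATCCCAAACGCCCGACACCATTTCGATAGCAACAACAGTAATGGTATTCCG
ACACTAGTCAGATGAGACCGGATCTTCGCCCTTATCCCCATGAGCTTTCACCTCACGAGTGTGTAGTAGTGCTATTTGGC
AGAATCCGCGAAGATTATGAGGACAGTAATCTTGGGTACCCGTGACGTTCCTTGAGCCCGCCGGCTTTCCGCATTGGAGA
GGGGTTCAACCGTCCACGGTACACAAGAATAACCCCCGGCGAGGGCCGCGGGAATTCAATGTGTAACACCCTAGATATGG
CCCGGTGCACGGATGAATATTGACATAAAATCCCTTCAATATAGATGGAACAGATAATAGGTTTATGCTCTGGGGCTGAG
TAATCACCTGCCCCCAGTGTGTTTACCATTCCTGGTGAGTATGAGCCCAGCGCTGTAGATTTTGAATCGTTGCCGTCTCC
ATCATGCTTTCACCATAGGATGCCGCTCGCTAACGGCTTTTATCCAGTAGGCTATGCGAATCCCCCAAGTCAGACGGCCT
CGGATTTGCGAATAAAAACTACATAAGGGTTTGGTGCTTTCGTCGTTAGAGAACTAGTATTTCCACCAAACATTACATAG
CGCCGCATGTACGTCGAGCCTGCGGATTACTCACTACGGAAATAAGGCCACGAAAACCCAGGAGTGGGGTAACAATATTC
AGTAAAGAGTCCGATGGAATTCGTATTGACGCTCCGCAGCGCGTGACCCGTGTCCCCCTAGCATCTGAATTTGGGGAATG
AGGGAAGCACTGGTCCTCATTGATGGGTGTCCATTACGGATCCTGCAGAAAGTTTCGAACATGTGCTTATACCAGGATAA
AGCTCTACTTGCGTAAATCAGGAGTGTGCCACCGCGAATAGACCACGGTCAATCTACCCCGGTCTTGAGGAGAGAGTTTA
AAAGGCTCGCGGGACCACGCTATTCCCTCCGGCCTCTCCTCATGCCACGCCCGCTGTTCTATGAATGCGAGAGTGTCATA
TCGGTAGGTAAAAGACATTATCACTACCGCAGGGTGATCTCGCACATTCGGTCCAATGGAGGTCACGCTGCTAGAGGTGT
AAGAATCTAGGAACGAAAGCCTGTCGGATAGGTATTTATTCGGTGACATTTAGCCTCACTTAAGCTACACCTACCTTCGC
GCTGTCAGGGGCAATCTAGCCATCTAACTCCCACGCCTGCACCCCTACGACACCTGCGACACGGTAAACGTTTTCGGATC
CAAGCCTCTGGGATAACGGAGTGCTCTCGGGATAACGACAACTTCACAGGGAGTATAATCAATTGCAATGATCGCGGCGG
TAGAGCATCATACGTGGTCAATTTGCAGCTGAGAGGCTCGGTGTAAAGGGCGGCTTAATGAGCACAGGTGGCCCGCTCTG
CGCTTTGTATCGTCGATTTTTGGACGTCCAGTCTAGGGCGAGTATTCAACTTGTTGATACAAGATCCTAGATTAGAGGCC
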
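>ancestral
AAGTTGGAGGCACAGGGTAGGGTAGGAAGGAGGCAGTGAAGTCCCCTAGCTAGTGCTAGAATGCCATTGGTTGGTTAGCG
GACATGCCCAAACAGAAAGCTCGTGTCTCCGACAGTAATGATACCAGTCAACTGAACCTATTCAGTCTGTTGGTAATCGC
GATCTATATATCTTGAATGTGACTATTCTCCTAGTGTTGACCCTTGCGTTCAGGCATGGGCCGCATCGCAACTAGTACAG
GCGCAGACTTCAGTGACGTTTGAAACCAGCAGCCCCTAATAACGAGATAGACTTGAGCCTAGTGAACAAACGTTAGATAG
ACCAAGCGCACCCGACCTTGTACACCGGCAGCATCGAAATTCACCAAGGGCCCGGGGCCCACTGACCGCCAAACTCACTT
TCGGTTGCCGCCACTTCGGCTAACTATCGACGTATCTTGAACTTCCGGAGATGACTGTTTAAGAGCGGCTAAGTGGGCGT
GGCAGCTGTCAGAATGACTCCGATTTGATTATCCCGGGTAATCCTTTACTAACGAATCGGTGTATTTCTTTTTCCGCGCA
CTAGGTGGGGTTGTTTCCCGATCTCGTCCGGCCCACGGGGTGACGAGAGAACCTGTGTCCCGCTTCCACGAGCTAGGCCG
TGTGTGTAGTCTACGAAGGATGCTTTCTAGGCCGAGCGCCAGTGCTCTAGGCATTCTTTGGCCCGATTCAAGGGTCCTTA
GACTTTCGTGTGTGGTCCCTAGATTGAGCAAATTGTCTAGCACAAACCTAGGTATCACGGCTGGCAAAAGGTTTGGCGTC
CAAGTCGATTTCCTTCGCTTTTGCACTCGACGGCATTGTTTGGCGCACTTAGGTAACCGCCCATGCTTACCGATGAAACA
GGTTGGCAGCGAGAGTCTCCCAGGTGCCGGCTTAATCTTGCCTATGTACTCGCCAGTCCTCACCAGAGATAGCTTTCTTC
TTCTCAGACATGTCCTCTTAGATGGCGGTGATGGCCTTGTACCCCTATCTGATTAATCTCCGCGTAAACGTCCGTTCTAC
CTAGCGGGTACTGTCGGTATTCGCAAGAGGGGTGTGTCAGCCCCCGTGCTTTTGCGTCCTTGAGTTTCAGTATTGAGAAG
TTAACTGCGATGAAGAGGACTCCTGGATCACCAGAAAAAGGGAACCGCCAGTGCGGGCTCCAGGCATGCAAGTTTGGGGG
TCGTCGTCCTACCTGGACGAATTTTCAGCTCCACCGTTGCCGGGTCCGCAACGTATCGAGTGGGACGCGAATGCGACTGA
TGAACAGCCGCATGACACACGGTATCTTGCACATGCTACCGCTATTAAACTGTACTAACCATGGGATCAGGAGGCGATCG
AGTGTTTAACAGGCGGTATGTGGTCGCTAGAATGGACACTCACGTACCCAATACTAGTGACATGAGCTAATGCAACATTG
ACCGCTGTTTAATCTCTTATGTCACGGTTGACTCGGCTTTAGGTGCATTTCCAACGTAGTACGTAGTACACCGTCGACAG
AACGCCCGACTACTACGTGTCCGGCCTCGTTTGCATTCGTTCATTGACTCAGTTAGACGGTACACTGGTAGCGTAAAACC
TATTGGGACTTTCATACGTTCTTTTGCGTAACCACCATAATTGTTACTACGTACTCCTAGACACTGAGTTTCTCAATCCC
TGCTTCGCATACAGCGCGATCGCGCCACAGGATCCTATCAGAAGGAACCATTTCCGGAACAAATTTCGATCAATTTCGGT
ACATGTAATGGGAGAGGGTTACCAATAAATCCCGCATGGGTCTAAGCACAACTTGAAAATAGAGTGAATCACAATTGATC
GTAAGTCAACGTATAAGTACTCCAGATCTCAGGCACCACATACCGCCGCGTCGCAAACTTCCTGGTCTTACGGTATAGCA
TGTAATACACGCACGATACAATAACTATTCAAAGACTGGTGCTATCGGCGGAAAAAGTGACCACCCTTTCGTGTCATCTC
TAATTAGCGTCGCTATCCATGCACCTATAATCGGCTACGCTGTGCACGACTCCGCGTGTCCATGGTAATCTCTAAAGCCA
TGCGCTATGGCAAAGCCACTTCTTATTAATTCGAAATAATGAGTGGCCGACGGTCGAGTCGGTTCCGAGTTATGCAGAGC
ATCTCGACGGCCATCATTACAATCTCATTTGAGTTTGCCGCTACTGATACATAAAGACAGTTCGCACGGGCCGAGGAAAT
TCAAGCGTATGTAGCCGGATATAACTTGGAGTGGCTTTAGCGAGTCGCATACACACATTTATTAAGCGCCGACCATGGGC
CTTCACTATCAAGCACACTAGGTAATCTAGCTTGCACAACAGAGTACCTTGAGTCAAGCTCATGTGGTTTGACGCAACTC
ATGGTAGACGGGAGCGGCCCATGCGTCCGTCTCGGGACCCATCTTGAGTGCCAGGAGGCCGTAACTTCCTATGAGATCGG
AAGATGTGGTTGGAGACACGTTGGTCATCCGAGTCCGTGCATCAAAGATTCACGTCTGTGTACTACGTTCACTCCGTCGC
TGCCGTTATGACCCGTCTAGCTTCTTCGCGTCAGACCGACCCCGATCCGAAGTGCCAAACTTGCCGGGAGTGGGCAGTAA
GCAAATAAATGAGGCCAGTCCCGTCGCTCATCACATGGGTACCGCCGATTTAAGCGTAACCTAGATGGGTCGCGAACGTG
GGGTGATTAATCCCAGGTCTTATTTAGACTTCTCGCGTTTAGACATGGAGTTGCGATGAATTGTAATCGGCCATGCCACA
GATTATGTAAATAACTTTTCGATATTATGTGCTTCAATTATATGAAGGCATGATGTCCTTCGGATATTACAATTATTTGC
GAGGATCCGCGAGGAAAAAGCGAACCTCCACACTGTGATAAACTCCCGTACTAGAACAACGCAACATCTTGGACCTCTCG
GATAAGGCTCGTAAGTAGGAACTAACTTCGGGTCTACGAGTTCTTGCCAGCGGGTCAACGTTCGAGATTGTCGCCCCCTC
CTGGGACGGACTCCAGTCCTGGAACCTTCCTGCCAGCCGGCTGCGTATATATTTGCTCCGGGGATAACATCTACGCGAGG
AAGTCATCTCGTGGATATTTGTTAGTCCGTTCGACGCAGGTGTAGGGTCCTAAGCCGACACGTCATACATCCCTGGATGA
TTTACGACTGTTAGGTTCTCGTCTGCTTAGGGTTCGAACTTGGTGGCGCACCTGTCTAGTTTAAACTCTTGGCTCTTAAG
ATGTATTCTCCGTTAATCCTGTTGACGTTTGGCGCGCATACGCACCAGATGGTTGTGCCGTTCTACCCAAATACGCAACG
AATTCCACGGATTATTCGTTTGCGCGATTTGCACCCTTAATGAGGCCTACGTGTAATTCTCAGAACTCCATGGGGTTGTG
GTACCAATCAGGTATAAGAACCTGTTGAGGCTCTAACGTTGGTACACGTTCATGGATGGCAATTTTATGGGCATACTAAT
AACGGTGTATACCAACCCAAGTTATTCGCATCCCTAGGCTACTATCAACCACCGCCGAGGGCCCCGCTATATCGGGATAC
GGATGTCCTCCCTCTTGCTCGGTAGGGTCCGGTCCTAACGACGCGGCGAAGAGGCCACGCAGAGTGCGTCTCATGCGGAC
CCTGAGGTTTCCAAGAAGACGAGGTAAAGCGCTGCGCCGTTACAGGTTGCCCAGAACTGATCTACATCTTAGAACACGGC
ATGAGCCTGGTGACCTCATAGAAACCTAGTTGTCTAGTACATACCGTTTATGATAGCACGAGCCGAAATGCGTGCTTTTA
CTCTCGACAGAATAACTTTTGGTCTCAGGCTACCTATGGAGCCCTAGTTGTCTGCTATTGTCGACATGGTAGCGATATGA
GCCTCTTGTCAAGAGTGACAACAACGACAAGCTGTACGACAGCCGTACAGACTGGGCCTATACGCAGCTAGTTTCAATGA
ATCCACGTCTAGAGATAGCGCGCCGAATGAAACGACTCGGCACTTTAGGAGTTGTAACCTACGCCAACTCGGCGGTACTT
GTTGGACCAACTGGCCCGGGACGTTGCTCTTGGTATCTATTGCAATGCCTCCTCTTGAAAAGTGATTTGCGGTCGATCTA
ACGAAGTCTAAAATGTACTCGGGATATTTCTGTTAGAGCCCTGGGTGATCATCCTGTAGTCTATTACTTGAGATGCCAAG
ACCAGTTATAACATGCTGAAAACCATGCTTACTCTGACAGGCTTGATCTGGCCGAGTCGATGTATGGGTTTATCGTGCGC
AAATCACTGAGCTTGCTGTATGAGTGGCGGTTTGGTAAATAGACACGTTTTGCATGATCCGGTCTAGGGCATCAGTCGGC
TCAGGATGATACAACTCGAAGAAAGTATCTCCCGGGAACTGTGTCGGTTCATTCGACATAAGGCACTCCAAGACTCTATA
TACGTGACCATCCGTTTACCGTGCACGCAGCATCTCGTTATTGCTGCCGCGCATTCAACTTGTCAGTGTAAACTTAGGTC
ACGGCCAGGGGTACCCACCTTTTTATCGCAGCTAATGAATTGTGTAAACAAAATTCCCTTGCTATGCATGCAGCCATAGA
CGCTTAGGGAGCGGGATAGGTACCACCGGCAACCTAAAGGGCACGTTTGTAATTTGTGGTGTGGGGCATGAAGCGCCAGC
ACGCGTCCCACCCCGATCGTCCAGGACCAATTCGGTGTAGCCAATTGAAGTGCCGCTGTAAAGATCATATTCGCCAGTAG
GGCGTGCGAAGTGCGCCAGTTTCATCCAGCCCTAATTCACCAGACGGGGTTAGTGATACCCAGCTATCGGGGTCACTCAG
TATTGCGTCATCTTTCGTCAGGGGCATAAGTTCACAACCAGTTCTGTAGAGGGCCCAAACGTTATTACAGTGTCATTGAT
CGTGACGACGCATTGGCACGGTATGGTTCGTTGACGTCGAATGCGGTTGTTACAAATCCTTTTTAACAAGGTTGCGCCTA
GAGCTAAAGCCTTACTGAGGCGCGGGTGTGTACGGTTGGGTCACGACGGTCAGAGTGTTAAGCCGAGATTCGTTAGTAGC
AGCAGACTCCGGTACGTAGGACCAGGCACAACGCGTTAAAAAGAACTCTTTTCACACCGCCCCCCCAATATGCACCAATC
CTGGAAGAATGGTGGCAGGTTCTTTACATCCCATATGGGATCTCCTGTTTAGCGAGAGCCCCTCGCTGTTAATCTCGATC
TTTCCGCATTATAGGACGGAAGTTCTGACGCGAGATGTGGTTGAATGCGGATGAGCCTTCCCCCACACATACCCTAGTCT
TCATACGTCTTCGGAGGTGACAGGTGTGATTACTCCTTTACGATCACAGAGACTCCTTTAAGGCCAAGAAAGGAGGAGTC
GAGGTGGACTTGCATCCGCTGCGCACAAGTCCGTGCTCGAACTCACACGGAACTAGAACTAATTCTGTAGAACTGAGTCT
AGATGTGGGGTTTGAAGGGCCACCAGAGTAACGACTGTTCGGTGCCTCGGCAGATAA
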
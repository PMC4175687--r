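>synthetic_puc19_length synthetic random sequence, 2686 bp (length stand-in for pUC19)
ACCGACAGAGGAACTGTTTTTGGATAGGAGTTGATTGATCCTTTGGACGAAAAATACGACCCGCAGTTGT
TTCTCGTCGGTCACGGAGGATCTCGAAAGGCATAGATTGACGCGCGACTCGCGGTTTTCTCAGTAAGGAT
AACCAGTGGGACTCTTCTGCAGGTGTTACTTTCCCAACTTCTGCCGGCTTTACTGTGCCAAACTTATGGT
GAGGGTGAGGGTACGGCACGGGAGGCTTCGCTTGGTTCGCTAAAACGTTTATCGAGGGTACGCGAATACA
TCTCGGCGGATGTTACCTTTCAGAAGGGGACCTGTGGAAGCACTTTAAATTTTGTGGCTGGCCAGTGGAA
GACCGGCAGCACATTCATCACCGAGAGTCTCTGATAAAGCCCGGTGGTTAACAGTTACGTTTACACGCGT
AGGTGGACTGTACTAAACCAAATGTGTGGACCTATACCCCTCCGTGTATGGTGGGGTCACTAACCAAAAT
GCTGCCTCGAAAATGGACGAATCGCCGGTGAGGTCCACACTTTTTTTCCGAGGGCATTGCCACTCCGACC
CGGCAGTGAGCTTCGTCATGAACCCTTACGCAACACGCATTTTACCGCCACGTACACTGCGTGCTCGCTT
GGCTAGTCCAACCGAGGGCAAGTTTCAGCTTCACAGTTCGTCATGTGCAATTTCCTCCCATTGCACTCTC
TCTTACATTTTACCATTGCATTTGCCGCAACCTAATTGCCGTGACGTACCTAATGTCTGTATTGGTCACG
CTGCCAACCCCCGACATGAGACCAAGCCCCTTAGGTGTGCCCTCCTCTTGCCCCCGCTATGTGAGCGTGA
CATGCGCTAGGGGCTGTATCCTTCTGGCGGTAGGTCTTCATAGTCGTCTTCTATATCTAAACTAAGGTGG
GCGTAAGTGACCATGGCTACCTGCGTATTCTTCGAAGATCACTAAGACGTCCAGCACCCGATACCCATAC
CTCCGGGCGGTCATATTAAGGTTAGTCCATATTATAAGGTATCTAACTACGCTTGTAGTCGAGAACAAGT
AGCGAAAGCGCATCGAGAATTATCGGTGCCACATGGACGGAGTAATGACACGCGCCGGCCGTATGCTTAG
TGGTTGCTGGCGACTCGCTTCGCAAGTGCCGGTATGGGGTAAAGGGGATAACGGTGTCCTTTGATCTTGT
TTAGAAGTGTACGGGTTCCTTACTAATGGCAAGTATGGGGGAAACTCGGGAAGGCGTCAATAGCGTTCCT
GTGAGTCGCGGTTCCCAATGCGATGAACTCTCGAGTTTTGGTTCCTATGAATATGAATAATGTCCGGGTA
TCCCTGCTGTTACACTGTCCAAATTCATGAGCAACTTTGGACGAAGGCGCTTGTCACTTGATCATAGATG
GGCTGCAATTTCAAGCGGCGCTTAGAGTCACTCCGGGAGGCGCCGGGGGGTAGCGTGCAGGAGTGGAGTT
ATTATTCTGCGTTCGTGACTAATAAGAGAGTTTCTTATTCAGGTTGGGTACCCAACAGCCATGAATTAGA
TGGAAATCGCATTTTGGTGGACTAAGTCTTGCACATGGGTATATCCGGCACCGTATCACATTGGCATACA
GCTTAGCGTGGGCTGCTCTTCATAACAGTTGCTACCTGGTACCCGGGTCCATACCGGTACTAATACCCCT
TAGGGTCGTCGCCGTTCATCATTCATTCAGCATGTAGGTAAATTATGCATACGCTTGCATTGTACGGCGA
GCCTGGGTGGGGTAAAATAAATGTATGTGTATCTATCCCGCAGACGAGAACGCCCGGGCTACAGGTACGA
TACGCAAGCCACATGATCAGCTACCACGAATTTAAATCCTGGAGCGTGGACGCCTGGCAAACTGTTCCTA
GGACAGCTCGCTAGTTAAGTCTTTCACAGCGAATCGTTGAGACTAGAAATTGTCAACTAATTGGGGGCCC
CGTGATACGTAGAGGTTAGGCTTTCGTTTACAGATAGATAGACCGGTCGACGCTCTAACAGTGGTATCAC
TCGGGGAGCTCCTGCGTGCTGATTCAGACTGAGTTCACCTCGGGTACACATAAGGCTCGAACGTTTACGT
AAGGACTTGGTTGTACACTCCCCTCACCGAATGTCAGCCGCCATCTGTCAGGTTTGTCATACTGTTCGAC
AGCCTGTCAGCATCAGCTTGAATCCTATTGATCCGATATCGCTATCAGCCACGTTGCAACTGCCCTTGTG
GGGACCGGCTTGAGTGCTCGAGTATCGTGATACTGTCATTCTGCGCGCCCCCGAGAGCGCCTTCATGCGG
CGGTGAATCACTTACTCGCTGGCATTCATACTTCCAGACCTCCTGGGGCTTCCGTGAGTTTCAGTTGTCT
AGAATGGGGCCACGCTTCACATACGAAACCTAAGGAAAGATGAATATAAACGACTTTGCTTCTGATGCCC
ACTCCCTTTCTAGATATAATTAGAGGAATCTCGAGCTAGCGCCGACGCTCGGTCCCCATGATCCCAGTTG
CAGGGGAAGGTTACGTCTCTCCCGAATTCACACCGGGAGGCTAATATGCTCTCTTCACTGATTCCAAACG
GTCCTCAATCGGCCATCGGAACCAGTTTAGTCGCCTGTCTCGTCGAAATCGTCAGCTACCCACCGAGTGA
TATCGGCCAAACAAACAGTCAACAAG
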
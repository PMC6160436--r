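>MT-TA
GAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCACGCCCTAAAGTACAATTAGG
>MT-TC
ATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAA
>MT-TD
GGTACCGCTGGCATATCACGCCTCCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCAC
>MT-TE
AAAGCCTCAAGCCGGAGTCTAGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAG
>MT-TF
CAGTTGAATATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCGAGG
>MT-TG
TATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATATCCTTAGTAG
>MT-TH
TCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCTCCTACAGACTCGT
>MT-TI
GCTACCGGACCATGCGACTCGAACATCAGATGGACAGACCTCGTAATAGCCGGGCCATGTAACACTGATGTC
>MT-TK
TCCGGGCAACTCATGACGAGCACCAGACCCGAGTGTTCCTGTTAGTTTTAGTTACACACGGAACGCTATC
>MT-TL1
GAGCGCGTAAGCGCCAACCCGCATTTACGAAGTACCCATCGTATGTAATAAGACCTCGAGTACGTCGGGA
>MT-TL2
CGTTGGCTGTGATGTTTTGATGAGCGAAGTTCGACGTTGCCGATGTTTACCCTAAGGGAGACGACATCA
>MT-TM
TCGCACGACTCGTCATTTGCATCATCTCCACTGCCCCGATGTCTGCTATGGACGGCTTCACCTGAT
>MT-TN
GTGGAGCGAGGGTACTGATAGATATACGACAATGCACGTAGTCTCGATACGTCATTGGTACGAACAGTTCG
>MT-TP
TATTCCCCATGTCTGGACCGACGTTAAGCTCATGTCTCAGGACGGAGAATGCAGCCCAACAGCTTGG
>MT-TQ
CCGGATCAAGCAGGATGAGAGGCACTTACTTTCCCCGCTACGATGCTTTGCACAAATTCTACCGCA
>MT-TR
TTGATCGTAGATTACACATTTTGATGGCATGGGTAATGGTGGAGCCAAACATCCAGCTAGCAGCT
>MT-TS1
GCAAGCTTTGCCTACGTGGAGTCTCTGTGAAATTCAGAGATACGCAGCTAATGGCCCCGCTTAA
>MT-TS2
CGGGTGCATCGGCACAGCCTCGTGCAGCCCTCACAAATTTCCGCCATCAGTGATTCAGTATTGTT
>MT-TT
TCACCGCAGTTACCGTGAAGTGCCGCCATATACACAGGTTCATGCTAGAGAAACTGCCACCCGGGCTTGCC
>MT-TV
AACCGGCAACGTGGCGTTGATTGACAGAGCTTCTTAAGCCGCTGATGTCCAAAAACTGAGTTAGTTCGAGA
>MT-TW
TAGTTGGATGTCGCACTAGAGGGAACAGCCATAGGACCGATACAGACAGTTCAATGGCGGATGCCC
>MT-TY
GCACCTGTATACACCTAGTATGTAAAAATTGAATACGAGAGGGGCACCCTTTTGCCCTCCCACTGTC
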
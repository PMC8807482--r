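>IGHV1-7*01|V|IGHV1
TATCTTACAAACGGAGGGCTCCGACAGATCTTATCAGACAAACTGCTTTACGGAACTAAAAAACGGCCCTCTGAGGACCTCTTTACCTGGAGTGCTACGCCAACCGTGGGACGCTCAAGTACAAGCTGGAACGTGACTGTGAAGCATCGGGGACGGTCGAAAGTACGTGACTCGTGTGGTAACAACCACGTACGCCCCTTGAGCGACAACCAATACTGTTTAAGGGCCTCCTGCAGCCCCGGCTCGGCTCGAGTCGCGCCCCCTTCACCTAGTACGACTTTTTATTACTGTGCAAGA
>IGHV1-26*01|V|IGHV1
ACGTCTCAGCTTAGCGCGCATGTTACCCCGAGGTGCAGCAGAAATGTCCTAATAACTGTTTTGCTTGAACCGACAGGTGTGTGCGTTGAACGTTCTCAACTCCCTCAGTCGCTGGATGGAATTATATCGAAGTCGACAACGGCCCCGGGGCATCAGCATGCTGGAGTTGGACGTCGGGGTCTAGGGGAACGTAAAACCAGTCGCGCCGGTCATCTCCATGTGTCGTACTGCGGGATAACGCCCGACTACCCGCACGACACATGGTTTATGTTAGTGTACACCTATTACTGTGCAAGA
>IGHV1-82*01|V|IGHV1
TGGGAAGGAGTGCAGAACGCACGCCTTATTCGCATGGTCAGAAGTACGGCTGCATGCGTGAACAAGTCTACTGAGCGTGTGCCTGCATTGTGCGAAACCCTCCTTATGAGATTAAACCAGGCAAAACCCGCAGGGCGATCAATGGCATATGCGTCCCGGCGCACCGTAACTTTGCTCAGGAGGCAGTGGTTAGATCTAACTTCACGGCAGAACCCCGCGTTCTGTAGGCCATTACGACCGAGGACCAGGATTGAAGAAGTACCATTTATCCCGACTGTCCGTTATTACTGTGCAAGA
>IGHV2-9*01|V|IGHV2
AAACCATCACTCTGCTGTGCTGCATACACGATTTTACCTAAGACGGGCCGGGGGGCAGTTACGTGCTCTGAAGGGTCTGTGAAATCATCTTCGCAGCGCATTCGTGCTAGTGCATCACGGTCGGGGGATTCTCCCCAAGCCCGCGAGCGGCCGCCGATCGACTTGAACATGCAGGCCCGCGCGGATGTTCTGGTAGGTAACCCGTCCTCAAGGGTCCGGATAGAATCGGAGTCCGATACCAAGCGAGTAAAAATACCGGGGATCGCCTCAGGGCTCCCCTCTTATTACTGTGCAAGA
>IGHV3-6*01|V|IGHV3
CGTATCCGCAATGGTCTTCCACGGGGGCTTGAAGGCCAATCAGTTATGCAGCGGACTAACTGGTTTGCCAAAGCGGAAAGCCATGACGTAGGGTGGTGGCAGAAGAAGAACTGTTTACAAATGTCGTTATACCCGCGGTCGCCTATTGTTTCGTGGAGGGAAGTCGCCATACGGAACAAGTCAGTGCGGGGTTCGGTAGGGGGGTTACTGCTCGACATAGGCCGACGGGGAGTCACCGCGAACCTATCGCTCACATTAGTTATTGATTACCAAGGGGCCACATATTACTGTGCAAGA
>IGHV5-6*01|V|IGHV5
CGGTACGAGAATCAAGGCATCCGTCTGGCTGCAATTGAGACTGCCAGCCCGTTCGCTGGTCGGGGCCGCTGCCTAAAGCACGTCCGAATCACCATCGACGGCAGTACCAAGTCGATACTAAACTACGTTTTCAGGGAATCAAGCCTACCGAAAGTGGATCCCCCGACTTCCGTGTTAGTGAGCAGATTCGCGCCGCTATCACCCGAGGTTATAATTATTCGTTCGGCGGATTTGGGTCAGACGGGTGCGCGCTTGAAAGCGGTGCTTGTATTATCAGTCCCTTATTACTGTGCAAGA
>IGHV6-3*01|V|IGHV6
GTAAGCTTTACGGTCACTGCTGTAGCGACCATGATCGATCAGAGCCCCCCTTGGGTCTATAGGGCTCCCTACGCTTCTGTTACACTGTGCCTGTCACGAGGGGGCATTCAATTACACATCAGCCCCGTCCACCCGCACCGCTCGAATCATGTCGGGATAGCGCAGCGCGGCAAACATGGGCGATACAGGCGTTCGGAAAAGTTTGGGATATGGGGGTTATACCAGCACCTGTCGGAGTCTTGTTTTCGTCCAGCTGGAATCCGCCATTCTGTTAGGGAAACATATTACTGTGCAAGA
>IGHV14-3*01|V|IGHV14
CTTACGGGCGTATCGTGTGGATACACCCAGCCAAGTAGCGTACTCTCGGAGAACTCGCCTATAATCGGAGTAACACGGACCTACCAGGGGATATACTACAAAGATTCTGGGGACTTTAGAAAGTCTCGAGGTCTTTCGGATCACAGGACAACTCACGCTCGGCGACATGGGTCCAGCTTTTGTGTCTGTGGAGTGGCTCGGAAAGTCGGTCGCAGTAAAATATTAAGTGTGGGGTTTCGCACCCTATCTAGCAAGTCATCGCGCTCTGTATTCTTACCGATGTATTACTGTGCAAGA
>IGHD1-1*01|D|IGHD1
ATCCGACCTCTA
>IGHD2-3*01|D|IGHD2
ACACCGGGAATAACG
>IGHD3-1*01|D|IGHD3
AATGGTTCGATT
>IGHD4-1*01|D|IGHD4
ATTCATAAGCGACAG
>IGHJ1*01|J|IGHJ1
GAACTATTACGATGGGGTCAAGGAACCTCAGTCACCGTCTCCTCAG
>IGHJ2*01|J|IGHJ2
GTGGCCAGCATATGGGGTCAAGGAACCTCAGTCACCGTCTCCTCAG
>IGHJ3*01|J|IGHJ3
CGGATCTATAGTTGGGGTCAAGGAACCTCAGTCACCGTCTCCTCAG
>IGHJ4*01|J|IGHJ4
CTGTTTGCTCTCTGGGGTCAAGGAACCTCAGTCACCGTCTCCTCAG
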
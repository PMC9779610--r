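>IGHD2-2|01|IGH|D||
GACCTGTACTCTCAGT
>IGHD3-3|01|IGH|D||
CCACCGGTCATTTTCCATTC
>IGHD3-9|01|IGH|D||
CAACGACTTAAATTATCAGGTCT
>IGHJ4|01|IGH|J|13|0
ATTGTCTGTCATTGGGTCGGCCACCGGACATTAGGTCACCGTCTCCTC
>IGHJ5|01|IGH|J|13|0
ATTGATCTGTTATGGCGATGGGTCCGGTATTCACAAGGTCACCGTCTCCTC
>IGHJ6|01|IGH|J|13|0
TATCACCACCCCTGGCTATATATTGGTTGGCAGATCGACAATGGTCACCGTCTCCTC
>IGHV1-18|01|IGH|V|289|0
TTGCGCCCCTGCTCACGTATCCCTCCTCAACTGTGCCCGCCTAGGTATGAGGTAATCCGA
AGTTCCCTAGGGTCCGGTCCTGTTGGGAGAAGAATCGCCTGCACACCGTGGATAACCGCA
TGGTATACAGAGAGGTCGCACGGAGTTGGCCTCTGTAATTGCATTACGGTACCTGAGCGG
CCCAAGGAATTGAAGGACAAGCCTCAGACGTGGACACAGTCTCACTTTTATTGGCGTGGA
GCATCTTGTGAAACGAGGTATATCGGGGTCTGCGTCCTCAAACTCTTATGTTCGGTT
>IGHV3-23|01|IGH|V|289|0
ATTCTTGAGCATGCCACTATCGCGCAAAATTTGTTACGGGCAACACTGCTCCGGGAACGG
GACGGCCAAAGTTCCATTATGAACCATGCGGTCTGCGAGGGCCAAGCAAGCGCTCAACCT
TTTCCAGATCTTCCACCAGTTTCACCAGGATGTCCGCGGGTCAGCATGCTGCGCCCACAG
GTCAATTTGTGTCCAGAACATAGCTACAAACTGATTGAATCCCATCAGAAATACCTTTCA
GTCCGTCAAACAAACAAGCAAACTGTGACTATCGTGCCACGCATTCATTGTGTATGG
>IGHV3-43|01|IGH|V|289|0
ATTCTCGTGCATGCCCCTATAGCGCAAAATTTGTTACGGGCAACACTGCTCCAGAAACGG
GACAGCCAAAGATCCATTATGAACCATGCGGTCGGCGATGGCGAAGCAAGCGCTCAACCT
TTTCTAGATCTTCTACCTGTTTCACCAGGATGTCCGCGGATCAGCATGCTGCACCCACGG
GTAAATTTGCGTCTGGAACCTAGCTATAAAATGATTGAATCCCATCAGACATACCTTTCA
GTCTGCCAAACAAAAAAGCAAACCGTGACTATCGTGCCACGCATGCATTGTGTATGG
>IGHV3-9|01|IGH|V|289|0
ATTCTCGTGCATGCTCCTATAGCGCAAAATTTGTTACGGGCAACACAACTCCAGCAACGG
GACAGCCATAGATCAATTATGAACCATGCGGTCCGCGATGGCGAAGCACGCGCTCAACCA
TTTCTAGATCTTCTACCTGTTTCACCAAGATGTCCGCGGATCAGCCAGCTGCACCGACGG
GTAAATTTGCGTTTGCAACCAAGCTATATAATGATCGAATCCCATCAGACAGACCATTCA
GTATGCCATACAAAAAAGCAACCCGTTACTATCGTGCCACGCATGCATTGTGTATGG
>IGHV4-39|01|IGH|V|289|0
CTCCGTTTCTTACATATCACTGCCGTGTTCAAGACGGGGTTCTTAGCCAACTCGGTGCCC
GGCTATCAAGACCGTATACGTCGACTTCGAAATCCGACTTTATGTTCTTTTCTCATTATT
GGGGGTCTTAGAGGGCAAGGGTACCGTATGTTGCCCGGTCAAGATCCGTTCAAAAGAGGA
CGCAACAACTCTACCTGGTCTAAAGATCCAGAAGGGGGTTTCTTACCCCCTCGATTCGTT
CGTCTTATTGACGAACATCGAAGTACTGACTCTCGTCTCTTTGTCAACTGTCGTGGT
>IGHV5-51|01|IGH|V|289|0
GGCACACCAGCCGGTGAGATGCGTGGGTATACAACCCTATACCTTACTGCGAACCAGCAA
CGCTTCTCTCTGTCTATTGGCGTTCCGCAACTTATATCCCGAGCCCAAGACCACCAAAGG
TACGATGCCACCCCCACGATTGTCCAAATTCTAATTGGCGGGGGTGTTCCTATACTTTTC
CTTCAGAATCCTTGTGAGGAAAGTTTATCGCGCTTGGGCTCCGTAACTCATACGAATTCG
ACATATTCAGCGACAGAGATTAGTTGCCGCCTCTGCCTCCATGTGTCATGTAGTGGC
>IGKJ1|01|IGK|J|10|0
CCCACGATCTTCTTGAAGCGGAACAGGGACAGTAGGATCCAGGGA
>IGKJ3|01|IGK|J|10|0
AGCATGCCGTTCGCCCAAACTTGTCATACTCCTACGTTACTT
>IGKV1-33|01|IGK|V|262|0
TGGCGGGGACATTCGGGAAGCTTGACAGAGGCTGCACAAACGCACAATGTAAGCGATACG
GCCTCGGGCGACTCGACGTGGAAAAACTCAGGGAACAACCTTCCATCTCAGCAGCTATAT
ATTGAAAATCTTTCCGCAGGGGGACGCAATGATAGCTTTCCGTTTCAACCACACTTCGGA
TGCCTAGCAAACAAATCAGCTCACTCTCTTTTCAGGATGAGCACGAACTTCGACAGTAGG
CCACGCGACTTCCGCAGGCTGTGTTCTTCT
>IGKV1-5|01|IGK|V|262|0
CTCACGCTCACCCATGAGCGTAGGTCGTGGTTGGTTCAAGAAGAGTCGTTAGCATTGAGA
CGGAAAGAGAGGGTTCTTAGATATCTGCTGTCTCATGGTATAACAGCTTATTATATACTA
CTACGCCTGCCGCGACCAAAAATCTTAAATTATGGCTCGATAATCAGCTCCTTCAGTGTG
CAACATACCATAGCCTCTGTCTTGTCTTCGAGCTGTGGGCCGATTGGCGAATCTAAGGTT
CCCTTTGCTAAGTCACCTGACTGTAAATCG
>IGKV3-20|01|IGK|V|262|0
CCGCCGGCTTCTCGGCGCTGCGTTTGTGATAAGTGCAGTTACATAAGTTGTTCTTCCGTA
CTACACTGTACCCTCCACGCGTTACTCGTGCTGCTTACATCATCATTATCGATCCATAAC
TACATTACGATGGTTCAATGGATGCATAAGCACGAGCTATCGTCCGGCTCACAGAGCGTA
GCATCTTATGTGTACCATAAACCGAGCCAACGATCCGTAAAGACAGAACAAATTTTAGAT
AAGGTGGACATTTCCGTCAACTGTCCATCC
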
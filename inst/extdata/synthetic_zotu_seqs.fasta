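>Zotu1
TCTCAGGAGCGATATTATGTCACTTAATACGTGACTGATCCGTCATTTCTTCAGACCTAAGTGGGTGGGGGATCTACCCA
>Zotu2
GGCACATACCTGTGAGGTAATTCAGATACGTACGACTAACGGCGACCGAGTCACTACCTGCGAGATTGGTTACTCGTTTG
>Zotu3
TGTTTCCTATCGTCCTCATCCTGAAAAGCCAGCATGCGCTCTGGAGTTAATATACCCAGATCGTAATTCTCATTCAGAAC
>Zotu4
GGGATTTACTCGGACCGGACAGGACCATCCCGGCCAGTAGGGCCCCTACCTAAACTAATTCTGGGTCTTTTACTCTTTAC
>Zotu5
CAAAGGAGAGCTGTATTCCACGCTAATCTCACAATTAGTAATCGGTTCTTCTGGAATCTCCTGTGAGAGTACGAGATCGC
>Zotu6
CGGGTTCCGGCGCTTACGGCGTTGGCGAAAGATTCGTATTTTACTTCTGGAGCCAGCGATTATCCGGATTCCGGTATCTC
>Zotu7
AGAACTTTCATCAACGCTGCCACAGAGGTTCACTCACTACTAGCGTGCACCGGTAGACGCATTGTGAGGGCACGGATCAG
>Zotu8
TGGATGGTCTCATGGGCGCGCCTTGCTGGGTCCTATGTCTTTAAAACCTACAGGGATTAGTATCACTCTATAGCAATGGT
>Zotu9
TAGTACTCAAGACCCAGGATACTCAAGAGGGATGCGATAGTTGAGATAACGGCGATTTCCACCTGAGCAGATCCTAAGCG
>Zotu10
TTCCTACATCGGGATCCATGGTCTATGGGGCACTTCTCAAGTGCTGCGTAGATTACCCCGTCGCAAAGACACGAGTGGGA
>Zotu11
AACTGGATGGGTTGGCAGTGGTCCCATTCATGACGTAATAAGCTCTCAAGTTAGCCGTAGCCAATCCTCCATAAGGTTAA
>Zotu12
CGCAAGCGGTCCTCTTCCACTGGTGTAAGATACTATCATGTCGGCAGATGCGGGGAGTTTTTGAGAGTTGGGCACTTCTA
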
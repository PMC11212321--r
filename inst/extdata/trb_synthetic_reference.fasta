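>TRBV9*01|V|58
GCTACATGACTGCGCAGAATTGTACCAAAAGTTTGTACCCTGTGTGCTAGCACTCAACTGTGCCAGCAGC
>TRBV20-1*01|V|58
CTTCCGCTTTCTGTGAGACGACCCCCTGAATGTCCCCCAAGAAGCTAACAGACATTTGTGCAGTGCTAGA
>TRBV12-3*01|V|58
TAGGCGTTGAGGTGATGCAGGAAACCCAGCGAGCTATTGAAAGTTGGTCAAGTAGCGATGTGCCAGCAGT
>TRBV15*01|V|58
AATTGAGAACTGAACTTGGGAATACTGTCTCAGTGATATCGATAAATCTCCAAGCGGTTGTGCCACCAGC
>TRBV7-8*01|V|58
ATGCGGGATAGTTGGGGTTATGGGATACAATCTACTGGACTGGTAGGGACCAGCCTCATGTGCCAGCTCC
>TRBV10-3*01|V|58
TCAGGACGGAATCAACCCGATCGGTATCAGGGTAGCTAACCGAAGCGCGTGCTTTTTCTGTGCCATCAGC
>TRBV7-6*01|V|58
TGGTCAACTCAGAGATAAGTGAAAACTATGCACGGCGGTGTACTGCAAATACAACGTGTGTGCCAGCTCT
>TRBV5-1*01|V|58
CAACCGCCGCCCAAACGGTGGATTGAAGATGGTGCTTTCTATAGTCGGTATCAGGATTTGCGCCAGCAGT
>TRBJ2-1*01|J|9
GAGCAGTTCTTCGGGCCAGGGACACGGCTCACCGTCCTAG
>TRBJ2-7*01|J|12
TACGAGCAGTACTTCGGGCCGGGCACCAGGCTCACGGTCACAG
>TRBJ2-3*01|J|15
ACAGATACGCAGTACTTCGGGCCAGGGTTGGAGTCGGCT
>TRBJ1-1*01|J|15
AACACTGAAGCTTTCTTTGGACAAGGCACCAGACTCACAG
>TRBJ2-5*01|J|12
GAGACCCAGTACTTCGGGCCAGGCACGAGGCTCCTGG
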
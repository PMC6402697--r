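>chr1
AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGA
ACCCCCTGCACGCCCTAAAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAAC
GTTCTAATAAACGACTTAGCAACAAGTCGCCTAGAAAGGTACCGCTGGCATATCACGCCT
CCCGCTTGCCGTCTTCAACTTCATGACCCTCGTGCATCACAAAGCCTCAAGCCGGAGTCT
AGGCTTTGAAACAGCTGAATAAATCGTGTGAATACGTGAGTCGTCGGAAAGCAGTTGAAT
>chr2
ATCTAACGACCCCTGCGCAAGGACACACTAGTCGCCCTTGAGAGCACTCCAGTCCAGGCG
AGGTATCCACGACGATACGACTCGGCTAGCAAACGCGCGGTTTATCTATGCAGCTAATAT
CCTTAGTAGTCGACCCCTGAGATGACCGGTCATCAGGCGGCATCCGACGCACCAACGGCT
CCTACAGACTCGTGCTACCG
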
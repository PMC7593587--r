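>grdA_like_cds_synthetic
ATGAGGCCTCAACTAGTTGTAAATTTCGCAGTCCTGGTCACCAAAGCATCATCCGTGGTA
GACGACATATGTTTGGGGGTCTGTTCGGAGTTACCTGCGCGCACGTCATTAGTCGAACAA
GGTGCGGAGGCTGATGATGCCCAGCTTATCGAGATAGCACACCGAGGAGCTGCCCCCAGC
TTAGAGGCAATTCTGTCATTTCCCCAAGCCGTAAGAAGAAAGAACCTGGCGACCACTTTT
TGACACGTGACGAGATTTCGTCACGCTTTTGCAGTAGTAGGCGTACAGGCCGGAGAGGAG
CCCTTAGTGGAAGACGCGAAGTTGGCTATGAGGGCTTATGTCCTTTCCAATGAGCTGGTG
CTGATTCTCCAAGCGGCAGATCAAAACTCGCTCAGCACTAGCGCCTCGATACCCATGATT
GACAACCAAATAGTCCCATTCGGCTATCTGCACCCTTTAAATGACAAACCCACGAAATCC
TAA
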
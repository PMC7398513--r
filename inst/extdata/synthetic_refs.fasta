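>COIB synthetic reference segment, COI positions 924-1303
TGGCCAATCCGATCGCGATAGGGCTGCTCTGAACAGATAGCCCCGCGTTGGCCTTTCAAACACTGAGTCAGAACAATAACACTCCAGCTTGAAAACTGCCTAATGTGGCTATGGTCCATTTATCATCCTGTCTGGTCCAATGTGCTCGTAAGTGGGTGACGCATCAGGACCCAAACTACGAGGTCACATAATCGCACGAACATAGTTCGCTTCATACTAGATTTAGAAGATATGTTGGAAATCGATCGCCGCAAGAAGTTGACGTGGGCAACCTGCTCGATCCGGCAGGGACACCTTGTCCACAAGTCTCGGACTGACCTCATGACGACTTTGGTCTTGGGGGACCAGGTGCTGCGCATGTTTGCGGTAGTCTTCAATCA
>TPI synthetic reference segment, Tpi exon4 (200 bp) + intron4 (172 bp)
ATTCTCAAATGACTTGTGCGATTTGTTGGGCAGCGTCCGCAGAGCCACGGTTCAGTACTGGACCAGTTGCCGTAGTCTAGTTGGGGCTGCCGCTAATGTCAATATACGGTCGCCTGTCCAACGAGTGGAATGGCTCGGATTAGCTCTCGGTGCTCGCCAGAACGACCCCATGCTATGTTACGCCCTTCCACACAGATATCTTGCGACGGTGGACCGACGCCTCGGACGTGTGCACGTCTCGTGGCCGGGATCTCCACCCTACTTGACATGATCAATTTAGCGACGTGCACCACCCGAACTTTCATTGGGATCTTAGAATGTATGATTATCAGTCTAATACGCTGCCGTGCCCTTTGGGTTACTTGATAGTTC
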
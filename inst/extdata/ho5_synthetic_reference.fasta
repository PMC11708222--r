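>HO5_synthetic_ref synthetic 586-codon reference CDS (make_reference seed 42); not a deposited gene sequence
ATGTATCTAACGGCTCGACTTGCAGATGAGGAACTCTTCCCCTGTGCACTCATGTCGGCTGAAGGCTCAGCGACCATGAC
TGAAGTACTGTCGGCCAGAGAGTGCGCACGTGGACGCCCAAGGAGTGCCAGTGCTCGCTACCTTCGCTGCGGGACTCTAG
GCCCAGTATCGTGCCTGGGCTGTCAAGTCAAGCCCCTCGTTGGATACCTCGGTTTTGCTTCGGACATCGGTCCATTCGCC
GCTACTGCTTCTTCAACTCGCAAAGTCACTCGCTCAGTAATAGAGGGTACCAGAAGGCAGTGGAAAGCAATTTTCACGCA
TGGGGAGTCAGGTAGGGAACGCGTGCCCATCTCTCGCTCGAGTCACTCAGATGACGGTCCCGACAAAGAGCAACCGGGAA
ACCTCCGAGATACGATTCAATCCTGCGGCAGTTCAACCCTTGCAATAAGGGCTGCGCCTGCTAGCGATATCGCTCGCACG
CTAACTTACCGAGTCTGTATGAGCCGCAATCTTTGCCGAGTCACACGACATCGCGGGATAACCACCGCTCTAATCACAGG
AGCTGCTGGGGAGTCAAAGCCACGCTGCGGTTTGCGGCGACGCCTAGGACGGCAACGTTTAACCAGAAGACGCGTGGCGA
CAATGTCTCGGTCTGCGCGGCTCAAAGGTAATGTAAGACCCGTGGTCATGTACCGGGCTTTTGCCGACTCAGAAGCAACC
TTGGCATCTAATTTCTGTGTTCAACTCGTACGATCGACTACGCATGCAAGGGACGGCAACGCGGACCGACTGGTTTCACT
TACTGACGCCCGTAATCTAAGCGCACTGGTGCATCTATCTGCTGGGGAAACAGTCTCTATTGCGAATAGTAATGTACGAC
ACATACTCCACCAACAGTACGAAATTAATTCCGCTCATCCGCACACAGTAAGGCCTCCGGAGCATAGCAATCGTGGGGAG
TTTCGAGGCGGTGGGCCGCGCAGCCACGTCAGATTTACGCACCGGCGCTCTTTTAAGAGCCTTAGCGAATGTGCCCGATG
CGTGTTGGTGAAACTAACCCCACAGAGCCTTAGTTCTTCTGGGTTAAGCAGAGTCACTGAGAAACCACATAACACCGGCG
CTAGTCAGCTGCTAGTACGTATTAAAGCAGGCGTGTGCAAAGAGAGAGGCCGCACTGGGCGGGAGTGCATAAGTGACCCT
CATGATAGAAAACTTAAGTCTTTAGCAGAGGTTCTGCGCGATACTACCTATTCGGAAAGGCCAGCTTCCCATCTTACAAT
CATATCTGTTCACCGTCAAAAAGACCTTCAAACAGAGCACATCCAAGCCATGAGGATATCTCCTACCACTCATAAGATAT
GTGCTATATGTGCTACTGGTCGTGCCGCATGCCTAACGATAGACGTATTGTGTAGCTGGGAGCTGATGATACTTTCAAAG
CTTCTATCTGTGCCTTTCACCATCCTTGCAGGTGTCGGCCCTCCAAACCAGCGCATTTCACCGTTTACACGATCTAAGAC
TACGGGCGTGGAGATGTGCAGTGGTTTTACGGCACTTATTCAGATCAAGCAGGTCCAGTCCGCCGATGAGATGCGACATA
CTCGCAGGCATATGTTGTGTTTTTTTTCACGGGTCAGCACGTATTTACCCTGCAGGTCGTTCATCGCTGCTTACCAACAG
GTCCAAATACCGTACACTTCAGTGCGTGCTCTAAGAACCCACTCTGCTAATCGTGCCGCTGATGGCACTGCTGAGTAA
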
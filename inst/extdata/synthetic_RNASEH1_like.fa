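>synthetic_RNASEH1_like_chr001
GCCTTTAAATAGCATTCCCCATTCAACAATCCTTATTCTACTCTCTTAGAGTCGTGGGAAGGATTGCCTA
CATGCGTCGCCTCCTCCTGTTGTTTTCGTGATGGGACTCGCTCTTTTCCATGCATCGTTGAAGCGTAATC
GCCCTCCATGCCTGTTACTTCCTTATGAACACGTCGGGGAAAGACACCCTGCCTTTGATGAATCTGCTCA
AAAACAGGAGCTATCGCAGGCCCCGGAGCGTCCACAGGGACTCACTAGGTTACGGCTACCCGAGCGTGAG
TCCGTGTCGCCAAGAGCTTTTATAGGCTGCTTTCCGCTGTGGGTATGTAGCCGCGGGGGAGACTGCATTG
TCAGTCTACGAATAGGTCCACGTTGCAGCGCCGGTGATGAAAACTACGTATGTGGGGAATGGAATCCGAA
CCTAAGTCAAAACCTTTCCTCGCCGTGTGTTAACTCGCTGTCTGGAAAGTTGCGCTCCACCTTTTATACC
GTTAACTACCGTTATACTTTTTGCAGTTTGAGTCGACTTCGTAAACCAGTCTTCTCCTTTCCTACGGCAC
ATTGCGCGTACCTTTGCGTTGTAGGCTTCACAACTGGCCCTAACCGGTGGATCAGCAATGAATATAGACT
TGCCCTGGCGTTTATAAGAGCACATAACTTGAGTTGTTTACATGGGGCTGAAAGGCAAGATTGCGCATTT
ATGTACGGAAATTTGCACGACCTTTCAAATAGTGCGGGACCCCTTAAATGCCCAATTTCGCTACAGGTAA
CTATTATTTTGCGTGTAGGCTTCTTTCCTATTGTTTATTTTAGTTATGCCAAGTCACTCAAAGCTCGCAG
TCTAATAGCATGGCAAGGTTCCAGTATCAACTTGCGGATCACCAACGGGACTTCGTGTGCTTGGTAACGA
CTCGTGGATCATCCTAGCCAACTTATGAATTCCCTTCCCATGCTCCGGAAAACCACGCGGCAACATGACG
TGAGCGCTGCAATCTCCTTCGTTCCCAACAAAACCCGGGCTTATTCCGCAGGATGCATCGTGGGAGATGT
TAACTGGGCTCGAGGGCTATCAATTGGCGAACGTACAATGAGGTACTTGTAGGGGAATATCGACGCGAGG
TCTCCTAGTGTCGAGTGGTCTTTAACGGTTGAGGCCCGTACGATCATTACATCACTGGGGCTTGTATTTC
CTGGGGACACTTTTAGGAGGATTTTCTATCCCGCATCCAAACCTTGGATTTGCCCGACCTAAACATGAGC
TTAAGAAATAGCTAGGGCCACCCGTATGATAGAAACCTTAAACGATCCACCTGCGCAATGTACGTAATAG
CCTCAGTAAGTGGGTGAATTTCTGTTAAGGATCGCATCTCTTACCATGCTCTCTAGCATAATATGGCCTA
GAGGCAC
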
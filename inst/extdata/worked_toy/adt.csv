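barcode,adt
AGACAGACCGCTGG-1,0.928
AGTTATAACCGGTT-1,0.812
AGATTAATAACAAT-1,0.913
GAGTCGGGATTCGT-1,1.11
TAAGGGAGAATTTC-1,1.193
GCGCCATTGAGTAG-1,1.071
TCCTGCCCACGTTG-1,0.962
AGAGCGCTTACTTC-1,0.916
TGAAAACCGATCAT-1,0.874
GTTCAATCTTGTAA-1,1.193
GAACAGAGGAAAAT-1,1.038
GCACACAACCGGAC-1,1.254
GCAGTGAGACAATG-1,0.855
TTCAGGTTGACACC-1,1.234
CACATCCGTGGCGT-1,1.176
TATCTCGTAAGCTT-1,1.195
AGCCGCGCCACCCT-1,0.904
GTCTTCGCCGTGTC-1,1.23
ACCAGAAACGTCGC-1,1.224
GGGATATACCTAGC-1,0.897
CGTCTCGGTGAGAT-1,4.062
TCGCGGCGTAGGCA-1,3.82
GTGGACTTCTCGAA-1,3.877
GTGCCTTTGGAAGC-1,3.945
GGGAGCTACCGAAC-1,3.894
TAAGGTGGCTAGTC-1,3.803
GACCTGTAGCTTTG-1,4.013
CCCGGTAGGGAACT-1,3.999
TACTATGGGTCTTC-1,4.234
GTGTGTGTGGTATG-1,3.938
ACCCAAGCAGAGAA-1,4.109
AGGCACCCGACTCT-1,4.119
TGCACTTAGCAAGC-1,4.287
TTCAGGCGTACTTG-1,4.037
GTGTATGCATTGGG-1,4.124
TCCTAGTCTCGCAC-1,4.012
AAAGATCAGATACG-1,3.982
GTGCGACTACCTTG-1,4.032
CATAGTGGCCTGAG-1,3.918
AGCCCTCCTGCATA-1,3.842
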
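gene,AGACAGACCGCTGG-1,AGTTATAACCGGTT-1,AGATTAATAACAAT-1,GAGTCGGGATTCGT-1,TAAGGGAGAATTTC-1,GCGCCATTGAGTAG-1,TCCTGCCCACGTTG-1,AGAGCGCTTACTTC-1,TGAAAACCGATCAT-1,GTTCAATCTTGTAA-1,GAACAGAGGAAAAT-1,GCACACAACCGGAC-1,GCAGTGAGACAATG-1,TTCAGGTTGACACC-1,CACATCCGTGGCGT-1,TATCTCGTAAGCTT-1,AGCCGCGCCACCCT-1,GTCTTCGCCGTGTC-1,ACCAGAAACGTCGC-1,GGGATATACCTAGC-1,CGTCTCGGTGAGAT-1,TCGCGGCGTAGGCA-1,GTGGACTTCTCGAA-1,GTGCCTTTGGAAGC-1,GGGAGCTACCGAAC-1,TAAGGTGGCTAGTC-1,GACCTGTAGCTTTG-1,CCCGGTAGGGAACT-1,TACTATGGGTCTTC-1,GTGTGTGTGGTATG-1,ACCCAAGCAGAGAA-1,AGGCACCCGACTCT-1,TGCACTTAGCAAGC-1,TTCAGGCGTACTTG-1,GTGTATGCATTGGG-1,TCCTAGTCTCGCAC-1,AAAGATCAGATACG-1,GTGCGACTACCTTG-1,CATAGTGGCCTGAG-1,AGCCCTCCTGCATA-1
TDE1,3,6,6,7,4,12,10,12,11,10,10,13,11,7,8,10,10,9,6,7,1,2,2,3,1,3,1,0,3,1,1,6,2,0,1,1,1,3,3,2
TDE2,1,6,3,1,1,3,0,1,2,2,0,0,3,1,4,1,2,6,1,0,3,5,8,7,10,7,16,10,6,8,3,5,4,5,11,6,8,6,10,4
TG03,0,2,5,3,5,3,3,9,2,4,3,1,5,2,4,3,0,3,3,2,1,4,6,2,3,3,3,2,5,7,4,2,2,4,4,4,2,7,3,3
TG04,3,3,3,1,1,2,6,1,3,5,3,4,2,2,3,5,2,2,2,2,2,0,2,3,3,4,2,1,3,3,5,1,3,1,1,2,5,1,0,2
TG05,1,3,4,3,3,1,2,5,4,2,0,1,2,2,6,2,1,2,1,2,3,4,6,2,6,0,5,4,1,1,3,4,4,4,4,6,2,1,3,1
TG06,7,3,8,5,1,1,3,4,3,2,2,6,9,5,4,2,2,2,4,4,3,2,7,8,5,6,3,3,2,6,4,1,3,3,6,4,1,2,1,4
TG07,0,1,2,3,1,5,5,2,2,3,4,4,3,7,3,0,5,3,5,3,0,0,4,5,3,2,5,2,1,6,2,2,3,3,6,1,2,2,6,5
TG08,4,5,5,1,4,0,6,1,5,2,2,5,3,2,1,2,2,3,0,5,3,0,2,3,3,1,3,2,3,5,2,3,4,2,3,3,3,3,0,5
TG09,2,1,3,3,4,8,5,3,6,5,3,0,5,3,1,3,1,4,5,1,5,3,7,2,3,1,1,4,0,3,4,6,1,5,5,3,1,3,5,3
TG10,3,3,5,3,5,6,3,3,4,4,3,4,3,7,1,6,8,4,5,4,7,0,2,7,3,0,5,4,4,5,4,3,3,3,7,4,0,4,3,3
TG11,2,7,2,0,3,5,2,1,2,6,3,3,0,2,2,1,6,3,4,2,2,4,3,3,4,3,2,2,3,2,5,4,6,2,3,4,8,2,0,6
TG12,3,5,6,2,5,2,1,5,4,4,1,5,3,2,3,3,2,2,2,3,2,3,5,3,8,5,1,1,0,1,4,2,1,4,0,3,5,1,1,2
TG13,4,4,4,2,2,1,1,4,3,3,5,2,2,3,0,3,2,5,7,2,1,2,5,1,2,4,3,4,5,4,2,2,2,2,4,2,3,4,1,2
TG14,1,3,3,3,1,3,2,6,4,4,1,2,2,7,3,5,2,4,4,2,3,3,7,3,2,1,2,4,1,5,6,3,4,6,4,6,2,3,0,7
TG15,1,3,5,2,4,2,3,2,2,2,0,4,3,5,5,2,2,3,3,1,3,1,2,5,6,0,0,6,3,3,2,3,3,4,2,1,6,1,0,2
TG16,5,2,1,1,2,3,3,3,3,3,0,1,3,5,1,6,1,2,4,2,5,2,2,4,1,3,5,5,1,1,3,2,3,4,2,4,4,3,4,3
TG17,2,1,1,0,2,2,4,3,2,3,6,1,2,9,0,3,3,3,6,2,6,3,3,6,2,4,2,4,0,1,1,4,3,2,5,2,2,2,2,2
TG18,3,2,1,5,2,4,3,0,4,5,2,2,5,3,3,2,3,3,3,2,1,1,1,4,3,2,1,1,5,3,4,6,4,6,7,3,4,3,3,5
TG19,4,3,3,5,1,4,3,2,3,4,1,0,2,5,4,2,1,4,3,3,4,2,3,5,6,3,3,1,4,5,3,4,2,2,6,5,3,4,2,1
TG20,3,2,3,3,0,4,1,1,5,2,1,2,0,3,2,2,4,2,1,2,0,2,6,0,3,3,7,2,2,3,6,6,1,2,2,2,4,1,2,2
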
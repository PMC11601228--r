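guide_id,gene,protospacer
NTC_1,NTC,GGATCGCGTCTAGTGCAGAT
NTC_2,NTC,GGGGTGAGGGTCCAATTCGG
ADNP_1,ADNP,GGTGGGAGAGGCGGCTTCAC
ADNP_2,ADNP,GCGTCGAGCGGTGCAGACAA
TREM2_1,TREM2,GCCGACCGCGGCAAGCAAGC
TREM2_2,TREM2,GCAGGAGGACGCAGGCCTAG
TCF4_1,TCF4,GCCTCCCCGGAGAAGAGAGT
TCF4_2,TCF4,GTGTGTCTGCGGATCTGTAG
TCF7L2_1,TCF7L2,GGGATCGAAATCCGGAGGAA
TCF7L2_2,TCF7L2,GGGAGCGGAGATTATTGACA
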
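# 32-locus rare-variant haplotype distribution (FAAH region), 32 haplotypes
haplotype	freq
00000000000000000000000000000000	0.7113
10000000000000000000000000000000	0.0034
00100000000000000000000000000000	0.0034
00001000000000000000000000000000	0.0034
00000010000000000000000000000000	0.0068
00000000100000000000000000000000	0.0034
00000000010000000000000000000000	0.0102
00000000001000000000000000000000	0.0034
00000000000001000000000000000000	0.0034
00000000000000001000000000000000	0.0034
00000000000000000001000000000000	0.0034
00000000000000000000100000000000	0.0264
00000000000000000000010000000000	0.0068
00000000000000000000000100000000	0.0306
00000000000000000000000010000000	0.0136
00000000000000000000000001000000	0.0034
00000000000000000000000000010000	0.0675
00000000000000000000000000000100	0.0036
00000000000000000000000000000010	0.0034
00000000000000000000000000000001	0.0038
01000000000000000000000010000000	0.0034
00000010000000000000000100000000	0.0510
00000000000110000000000000000000	0.0034
00000000000000000000101000000000	0.0034
00000000000000000000100000010000	0.0009
00000000000000000000100000000100	0.0033
00000000000000000000010000000100	0.0034
00000000000000000000000100010000	0.0034
00000000000000000000000000010001	0.0030
00010010000000000000000100000000	0.0034
00000010000000000000010100000000	0.0034
00000010000000000000000100000100	0.0034
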
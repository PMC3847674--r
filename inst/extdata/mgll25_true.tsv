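# 25-locus rare-variant haplotype distribution (MGLL region), 22 haplotypes
haplotype	freq
0000000000000000000000000	0.7995
1000000000000000000000000	0.0509
0100000000000000000000000	0.0034
0010000000000000000000000	0.0436
0000100000000000000000000	0.0034
0000010000000000000000000	0.0034
0000000010000000000000000	0.0073
0000000000100000000000000	0.0034
0000000000000010000000000	0.0034
0000000000000000001000000	0.0068
0000000000000000000100000	0.0068
0000000000000000000010000	0.0034
0000000000000000000001000	0.0102
0000000000000000000000100	0.0034
0000000000000000000000010	0.0102
1010000000000000000000000	0.0040
1000000010000000000000000	0.0029
0000011000000000000000000	0.0204
0010000000000100000000000	0.0034
0010011000000000000000000	0.0034
1000011000000000000000010	0.0034
1000000000011000000001001	0.0034
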
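name	sequence	target_group
Megenus_487	GCCGGGGCTTTTTCTGTTGGT	whole genus
MegPoly_66	GCAAGCCCCAATTTTGTTCGT	Clade A + Clade D
MegairaB_76	YCTGAAGCAAGCTCCAGC	Clade B
MegVene_95	CCGTTTGCCACTAACGAC	Clade C
MegairaE_69	GGTGCTTCGTCCAAAGGCATC	Clade E
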
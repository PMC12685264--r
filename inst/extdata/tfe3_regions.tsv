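name	kind	ordinal	length
exon1	exon	1	246
intron1	intron	1	2542
exon2	exon	2	113
intron2	intron	2	1047
exon3	exon	3	303
intron3	intron	3	665
exon4	exon	4	245
intron4	intron	4	83
exon5	exon	5	104
intron5	intron	5	3769
exon6	exon	6	117
intron6	intron	6	352
exon7	exon	7	56
intron7	intron	7	186
exon8	exon	8	75
intron8	intron	8	1921
exon9	exon	9	147
intron9	intron	9	800
exon10	exon	10	1875
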
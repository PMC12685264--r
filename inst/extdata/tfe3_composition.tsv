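name	at_fraction	gc_fraction	n_A	n_C	n_G	n_T	length
exon1	0.292683	0.707317	39	105	69	33	246
intron1	0.479544	0.520456	674	744	579	545	2542
exon2	0.522124	0.477876	30	21	33	29	113
intron2	0.453677	0.546323	241	245	327	234	1047
exon3	0.349835	0.650165	59	86	111	47	303
intron3	0.481203	0.518797	197	223	122	123	665
exon4	0.314286	0.685714	27	65	103	50	245
intron4	0.566265	0.433735	24	7	29	23	83
exon5	0.480769	0.519231	23	26	28	27	104
intron5	0.516317	0.483683	1059	959	864	887	3769
exon6	0.444444	0.555556	25	30	35	27	117
intron6	0.511364	0.488636	107	76	96	73	352
exon7	0.517857	0.482143	6	14	13	23	56
intron7	0.435484	0.564516	53	33	72	28	186
exon8	0.466667	0.533333	14	18	22	21	75
intron8	0.49089	0.50911	439	552	426	504	1921
exon9	0.394558	0.605442	20	45	44	38	147
intron9	0.5375	0.4625	231	180	190	199	800
exon10	0.427733	0.572267	390	514	559	412	1875
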
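region	length	breakpoints	max_abs_ddG	g4_count	palindrome_count	g4_density	palindrome_density
exon1	246	0	10.83	2	10	8.13	40.65
intro1	2542	2	15.67	29	85	11.41	33.44
exon2	113	0	10.65	2	6	17.70	53.10
intro2	1047	0	11.39	6	25	5.73	23.88
exon3	303	0	7.94	1	12	3.30	39.60
intro3	665	0	8.97	4	18	6.02	27.07
exon4	245	1	11.41	2	14	8.16	57.14
intro4	83	4	7.08	0	1	0.00	12.05
exon5	104	1	9.22	2	3	19.23	28.85
intro5	3769	23	33	24	111	6.37	29.45
exon6	117	0	5.91	0	5	0.00	42.74
intro6	352	0	6.33	5	14	14.20	39.77
exon7	56	0	3.65	1	3	17.86	53.57
intro7	186	0	7.35	2	3	10.75	16.13
exon8	75	0	4.61	0	3	0.00	40.00
intro8	1921	0	9.31	19	56	9.89	29.15
exon9	147	0	7.3	2	3	13.61	20.41
intro9	800	0	7.85	1	15	1.25	18.75
exon10	1875	0	10.47	9	55	4.80	29.33
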
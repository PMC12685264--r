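sample_id	region_name	genomic_coord	resolution	source
1	intro5	NA	region	rna_seq
2	intro4	48895908	region	dna_seq
3	intro5	48891945	region	dna_seq
4	exon4	48895784	region	dna_seq
5	intro5	48892022	region	dna_seq
6	intro5	NA	region	rna_seq
7	intro4	48895666	region	dna_seq
8	intro4	NA	region	rna_seq
9	intro5	NA	region	rna_seq
10	intro5	48895230	region	dna_seq
11	intro5	NA	region	rna_seq
12	intro5	48893163	region	dna_seq
13	intro5	NA	region	rna_seq
14	intro5	48895306	region	dna_seq
15	intro5	NA	region	rna_seq
16	intro1	NA	region	rna_seq
17	intro4	NA	region	rna_seq
18	intro5	48891274	region	dna_seq
19	intro5	48892310	region	dna_seq
20	exon5	48895555	region	dna_seq
21	intro5	48893347	region	dna_seq
22	intro5	48895530	region	dna_seq
23	intro1	NA	region	rna_seq
24	intro5	48892028	region	dna_seq
25	intro5	48895667	region	dna_seq
26	intro5	48894609	region	dna_seq
27	intro5	48894282	region	dna_seq
28	intro5	NA	region	rna_seq
29	intro5	48894455	region	dna_seq
30	intro5	NA	region	rna_seq
31	intro5	NA	region	rna_seq
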
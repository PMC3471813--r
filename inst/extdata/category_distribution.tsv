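category	original_n	original_pct	training_n	training_pct	classified_n	classified_pct
Amino acid biosynthesis	4102	2.53	90	2.54	115	2.20
Biosynthesis of cofactors, prosthetic groups, and carriers	5482	3.39	148	4.18	179	3.42
Cell envelope	227	1.40	47	1.33	41	0.78
Cellular processes	17778	10.99	353	9.97	283	5.41
Central intermediary metabolism	2517	1.56	78	2.20	92	1.76
DNA metabolism	9238	5.71	287	8.10	344	6.57
Energy metabolism	27132	16.77	744	21.01	1363	26.04
Fatty acid and phospholipid metabolism	4823	2.98	118	3.33	253	4.83
Mobile and extrachromosomal element functions	7716	4.77	123	3.47	119	2.27
Protein fate	11611	7.17	359	10.14	550	10.51
Protein synthesis	9044	5.59	140	3.95	149	2.85
Purines, pyrimidines, nucleosides, and nucleotides	2678	1.65	62	1.75	77	1.47
Regulatory functions	18817	11.63	247	6.97	327	6.25
Transcription	2816	1.74	86	2.43	50	0.96
Transport and binding proteins	25368	15.68	363	10.25	757	14.46
Mix category	8297	5.13	297	8.39	536	10.24
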
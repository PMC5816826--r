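protein_id	putative_function	size_aa	sp_length	cysteine_pct	in_dothideomycetes	lfc_semisterile_pine	lfc_invitro_pine	lfc_invitro_poplar	extramatrical	sclerotia	duplication_partner
28058	-	209	20	8.17	Yes	2.49	-0.92	2.5
331593	-	81	21	6.25	No	1.42	-0.02	-0.7
552209	Cupin domain, manganese ion binding/spherulin-like	275	20	1.46	Yes	4.41	2.1	0.87
634429	Protein of unknown function DUF4237	224	18	1.79	Yes	2.43	3.6	3.6	x	x
636312	Duplicated gene	249	19	3.23	Yes	1.93	0.46	0.74			660403
658610	Ubiquitin 3 binding protein But2, C-terminal	186	19	1.08	Yes	3.55	-0.25	-0.82		x
659287	-	136	20	7.41	Yes	3.66	1.2	0.6
659858	Duplicated gene	58	19	3.51	No	4.3	0.95	1.2			660401
660401	Duplicated gene	58	19	3.51	No	8.08	9.4	5.9			659858
660403	Duplicated gene	249	19	3.23	Yes	6.53	0.68	-0.074			636312
661585	-	194	22	4.66	Yes	5.4	3.5	2.3		x
664950	-	72	19	0	No	1.21	0.21	-0.39
666290	-	180	22	10.61	Yes	2.95	2	3		x
667330	NTF2-like domain, Polyketide cyclase SnoaL-like domain	172	19	0.58	Yes	3.75	3.8	2.9		x
668273	-	204	19	0.99	Yes	3.53	2.7	3.4		x
670497	-	199	17	5.05	Yes	2.89	-0.041	0.15
677232	Ubiquitin 3 binding protein But2, C-terminal	204	18	1.48	Yes	7.53	-6.2	-1.6
679266	Duplicated gene	131	20	0	No	5.94	2.5	4.9		x	693798
680403	-	135	20	1.49	No	7.88	1.5	5.4		x
693798	Duplicated gene	239	21	0.84	No	7.18	8.4	6.5		x	679266
698167	Fusarium secreted in xylem protein 1	259	23	3.88	No	8.21	8.1	6.9		x
723230	-	96	23	2.11	Yes	2.52	0.3	0.26
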
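gene_id	strain_01	strain_02	strain_03	strain_04	strain_05	strain_06	strain_07	strain_08	strain_09	strain_10	strain_11	strain_12	strain_13	strain_14	strain_15	strain_16	G_stellatum	L_palustris
28058	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1
331593	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	0	0
552209	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
634429	1	1	1	0	1	1	1	1	0	1	1	1	1	1	1	1	0	1
636312	1	1	1	1	1	1	0	0	0	0	0	1	1	1	1	1	1	1
658610	1	1	1	1	1	1	1	1	1	1	1	1	0	0	1	1	1	0
659287	1	1	1	1	0	1	1	1	1	1	1	1	1	1	1	1	1	1
659858	1	1	1	1	1	1	1	0	1	1	1	0	0	0	0	0	0	0
660401	1	1	1	0	1	1	0	1	1	1	1	1	1	1	1	1	0	0
660403	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0	0	1	0
661585	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0
664950	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0
666290	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0
667330	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1
668273	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
670497	1	1	1	1	1	0	1	1	1	1	1	1	1	1	1	1	1	1
677232	1	1	1	1	0	0	1	1	1	0	1	1	1	1	1	1	0	0
679266	1	1	1	1	1	1	1	0	0	1	1	1	0	1	1	1	0	0
680403	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	0	0	0
693798	1	1	1	1	1	1	1	1	1	0	0	1	1	0	0	1	0	0
698167	1	1	1	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
723230	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	0	1
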
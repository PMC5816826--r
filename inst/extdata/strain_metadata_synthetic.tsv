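strain_id	clade	country	forest_type
strain_01	5a	Switzerland	Ps
strain_02	5a	Switzerland	Ps
strain_03	5a	Switzerland	Ps
strain_04	5a	Switzerland	Ps
strain_05	5a	Switzerland	Pa
strain_06	5a	France	Fs
strain_07	5b	Switzerland	Pa
strain_08	5b	France	Mx
strain_09	5b	Poland	Ps
strain_10	5b	Switzerland	Fs
strain_11	5b	Finland	Ps
strain_12	6	Switzerland	Pa
strain_13	6	Poland	Mx
strain_14	6	Finland	Pa
strain_15	6	France	Fs
strain_16	6	Switzerland	Mx
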
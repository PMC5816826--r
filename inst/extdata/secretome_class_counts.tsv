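sp_class	count
SSP	227
CAZyme	120
lipase	13
protease	27
otherSP	208
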
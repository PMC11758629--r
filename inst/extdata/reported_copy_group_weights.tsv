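scaffold	pos	copy_group	relative_copy	mean_weight_g
NW_020871546.1	601107	max	9	33.47
NW_020871546.1	601107	min	-6	25.32
NW_020872788.1	580574	max	7	9.86
NW_020872788.1	580574	min	-13	16.98
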
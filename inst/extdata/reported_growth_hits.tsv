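scaffold	pos	unit	p_value	r	genes
NW_020868344.1	307127	CA	1.91e-4	0.59	LOC113803219
NW_020868539.1	104464	A	3.43e-4	0.52	LOC113820924,LOC113821003
NW_020868569.1	296214	AT	2.85e-4	-0.66	LOC113822999
NW_020868683.1	279909	TAA	3.30e-4	0.55	LOC113802910
NW_020869000.1	338751	A	1.33e-4	0.51	LOC113805488,LOC113805487
NW_020869150.1	290225	T	2.93e-4	0.53	LOC113807065
NW_020869421.1	132288	TAA	1.84e-4	-0.51	LOC113809390
NW_020870537.1	94961	AG	3.85e-5	-0.53	
NW_020871546.1	601107	TAA	8.95e-5	0.60	LOC113825946,LOC113825948
NW_020872587.1	7026	A	1.92e-4	0.61	
NW_020872788.1	580574	A	2.52e-4	-0.55	LOC113800912
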
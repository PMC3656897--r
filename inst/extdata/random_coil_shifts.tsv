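residue	atom	shift_ppm	source
Ser	HB	3.79	random-coil
Ser	HB	3.95	random-coil
Thr	HB	4.22	random-coil
aThr	HB	4.22	random-coil
Ser	HA	4.47	random-coil
Thr	HA	4.35	random-coil
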
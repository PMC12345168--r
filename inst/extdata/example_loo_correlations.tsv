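left_out	subset	n	rho_s	rho_corrected
Pa	Aa_624	144	0.74	0.82
Aa_624	Aa_624	144	0.54	0.76
Pg	Aa_624	144	0.50	0.74
Sg	Aa_624	144	0.55	0.75
Sa	Aa_624	144	0.58	0.71
Pa	Aa_Y4	142	0.73	0.82
Aa_Y4	Aa_Y4	142	0.39	0.75
Pg	Aa_Y4	142	0.50	0.76
Sg	Aa_Y4	142	0.55	0.79
Sa	Aa_Y4	142	0.57	0.70
Pa	Aa_VT1169_BY	142	0.74	0.83
Aa_VT1169_BY	Aa_VT1169_BY	142	0.41	0.74
Pg	Aa_VT1169_BY	142	0.49	0.77
Sg	Aa_VT1169_BY	142	0.54	0.76
Sa	Aa_VT1169_BY	142	0.57	0.71
Pa	Aa_VT1169_TY	142	0.73	0.83
Aa_VT1169_TY	Aa_VT1169_TY	142	0.49	0.77
Pg	Aa_VT1169_TY	142	0.49	0.77
Sg	Aa_VT1169_TY	142	0.54	0.76
Sa	Aa_VT1169_TY	142	0.57	0.71
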
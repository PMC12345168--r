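condition	low	high
Pa	151	17
Aa_Y4	70	4
Aa_624	71	0
Aa_VT1169_TY	45	10
Aa_VT1169_BY	43	14
Pg	39	7
Sa	23	8
Sg	20	9
Si	40	5
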
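name	role	species	locus
BsKinA	HISKA_LIKE	Bacillus subtilis	KinA
Bs0F	REC	Bacillus subtilis	Spo0F
Bs0B	HISKA_LIKE	Bacillus subtilis	Spo0B
Bs0A	REC	Bacillus subtilis	Spo0A
Dt1918	HISKA_LIKE	Desulfotomaculum acetoxidans	Dtox_1918
Dt0F	REC	Desulfotomaculum acetoxidans	Spo0F
Dt0B	HISKA_LIKE	Desulfotomaculum acetoxidans	Spo0B
Dt0A	REC	Desulfotomaculum acetoxidans	Spo0A
Ca0903	HISKA_LIKE	Clostridium acetobutylicum	CA_C0903
Ca3319	HISKA_LIKE	Clostridium acetobutylicum	CA_C3319
Ca0A	REC	Clostridium acetobutylicum	Spo0A
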
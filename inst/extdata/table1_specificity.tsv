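species	locus	role	pas	signature
Bacillus subtilis	KinA	kinase	Yes	TAGFQL
Bacillus subtilis	KinB	kinase	No	TVGFQL
Bacillus subtilis	KinC	kinase	Yes	TSGFQI
Bacillus subtilis	KinD	kinase	No	TGGFQL
Bacillus subtilis	KinE	kinase	Yes	TAGFQL
Bacillus subtilis	Spo0F	spo0f	NA	QGILEVD
Bacillus subtilis	Spo0B	spo0b	NA	QLGNSL
Bacillus subtilis	Spo0A	spo0a	NA	NELLEYD
Desulfotomaculum acetoxidans	Dtox_0091	kinase	Yes	TTGFQM
Desulfotomaculum acetoxidans	Dtox_1564	kinase	No	TAAFEL
Desulfotomaculum acetoxidans	Dtox_1918	kinase	Yes	TTGFQL
Desulfotomaculum acetoxidans	Dtox_2569	kinase	Yes	TTGFQM
Desulfotomaculum acetoxidans	Dtox_3081	kinase	Yes	TTGFQF
Desulfotomaculum acetoxidans	Dtox_3426	kinase	Yes	TTGFQL
Desulfotomaculum acetoxidans	Dtox_3834	kinase	Yes	TTGFQM
Desulfotomaculum acetoxidans	Spo0F	spo0f	NA	QGILEVD
Desulfotomaculum acetoxidans	Spo0B	spo0b	NA	QVGLQL
Desulfotomaculum acetoxidans	Spo0A	spo0a	NA	NEFLDFD
Clostridium acetobutylicum	CA_C0323	kinase	No	NVSAQV
Clostridium acetobutylicum	CA_C0903	kinase	Yes	NISAQL
Clostridium acetobutylicum	CA_C3319	kinase	No	SVGLQL
Clostridium acetobutylicum	Spo0A	spo0a	NA	NEFIDYD
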
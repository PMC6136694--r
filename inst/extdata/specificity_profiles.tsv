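profile_id	role	fasta	ref_name	anchor	offsets
hiska_default	HISKA_LIKE	hiska_refs_synthetic.fasta	EnvZ_syn	20	-2,3,4,7,8,11
hiska_default	HISKA_LIKE	hiska_refs_synthetic.fasta	RstB_syn	23	-2,3,4,7,8,11
hiska_default	HISKA_LIKE	hiska_refs_synthetic.fasta	CpxA_syn	20	-2,3,4,7,8,11
rec_default	REC	rec_refs_synthetic.fasta	OmpR_syn	57	-4,7,8,30,31,48,49
rec_default	REC	rec_refs_synthetic.fasta	RstA_syn	57	-4,7,8,30,31,48,49
rec_default	REC	rec_refs_synthetic.fasta	CpxR_syn	60	-4,7,8,30,31,48,49
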
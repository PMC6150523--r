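id	generation	mother_id	father_id	coi	nuc_mat	nuc_pat	m_status
EfMp_0	0	NA	NA	f	F	F	Mp
poc_01	1	EfMp_0	EfMp_0	f	F	F	Mp
poc_02	1	EfMp_0	EfMp_0	f	F	F	Mp
poc_03	1	EfMp_0	EfMp_0	f	F	F	Mp
poc_04	1	EfMp_0	EfMp_0	f	F	F	Mp
poc_05	1	EfMp_0	EfMp_0	f	F	F	Mp
poc_06	1	EfMp_0	EfMp_0	f	F	F	Mn
poc_07	1	EfMp_0	EfMp_0	f	F	F	Mn
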
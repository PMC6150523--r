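id	coi	nuc_mat	nuc_pat	m_status
aAA41	a	A	A	Mp
aAA45	a	A	A	Mp
syn_aAA_01	a	A	A	Mp
syn_aAA_02	a	A	A	Mp
syn_aAA_03	a	A	A	Mp
syn_aAA_04	a	A	A	Mp
syn_aAA_05	a	A	A	Mp
syn_aAA_06	a	A	A	Mp
syn_aAA_07	a	A	A	Mp
syn_aAA_08	a	A	A	Mp
aAF101	a	A	F	Mp
syn_aAF_01	a	A	F	Mp
syn_aAF_02	a	A	F	Mp
syn_aAF_03	a	A	F	Mp
syn_aAF_04	a	A	F	Mp
syn_aAF_05	a	A	F	Mp
syn_aAF_06	a	A	F	Mp
syn_aAF_07	a	A	F	Mp
syn_aAF_08	a	A	F	Mp
syn_aAF_09	a	A	F	Mp
syn_aAF_10	a	A	F	Mp
syn_aAF_11	a	A	F	Mp
syn_aAF_12	a	A	F	Mp
syn_aAF_13	a	A	F	Mp
syn_aAF_14	a	A	F	Mp
syn_aAF_15	a	A	F	Mp
syn_aAF_16	a	A	F	Mp
syn_aAF_17	a	A	F	Mp
syn_aAF_18	a	A	F	Mp
fFF42	f	F	F	Mn
fFF61	f	F	F	Mn
fFF112	f	F	F	Mn
syn_fFF_01	f	F	F	Mn
syn_fFF_02	f	F	F	Mn
syn_fFF_03	f	F	F	Mn
syn_fFF_04	f	F	F	Mn
syn_fFF_05	f	F	F	Mn
syn_fFF_06	f	F	F	Mn
syn_fFF_07	f	F	F	Mn
syn_fFF_08	f	F	F	Mn
syn_fFF_09	f	F	F	Mn
fFF_158/190	f	F	F	Mp
fFA_143/159	f	F	A	Mp
syn_fFA_01	f	F	A	Mp
syn_fFA_02	f	F	A	Mp
fFA_149/194	f	F	A	Mn
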
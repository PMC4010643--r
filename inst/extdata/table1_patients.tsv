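tumour	age	sex	smoker	stage	grade
4062	69	F	Ex	pTa	G2
4070	74	M	Passive	pTa	G2
4078	56	M	Current	pTa	G2
4101	81	M	Ex	pTa	G1
4121	71	F	Never	pTa	G2
635	85	M	Ex	pT1	G3
709	73	F	Current	pT1	G3
745	83	F	Ex	pT1	G3
799	87	M	Ex	pT1	G3
3010	78	F	Ex	pT1	G3
451	78	M	Ex	pT2	G3
615	75	F	Ex	pT2	G2
2010	76	F	Ex	pT2	G3
3008	82	F	Ex	pT2	G3
3034	77	F	Never	pT2	G3
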
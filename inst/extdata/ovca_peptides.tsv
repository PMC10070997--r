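gene	peptide	hla_allele	sources	best_ion_score
PRAME	QLLALLPSL	A*02:01	TMD8+A2;EBV-5098	37
PRAME	LYVDSLFFL	A*24:02		NA
PRAME	SPRRLVELAGQSL	B*07:02	COV413b;AML-6711;TMD8+B7;EBV-5098	30
PRAME	MPMQDIKMIL	B*07:02	TMD8+B7;AML-6498	25
PRAME	SPSVSQLSVL	B*07:02	COV413b;EBV-5098;TMD8+B7;AML-3374;U266	65
PRAME	LPRELFPPL	B*07:02	EBV-5098;K562+B7	26
PRAME	MPMQDIKMIL	B*35:01	TMD8+B7;AML-6498	25
PRAME	LPRELFPPL	B*35:01	EBV-5098;K562+B7	26
PRAME	YEDIHGTLHL	B*40:01	COV362.4;U266	42
CTCFL	CSAVFHERY	A*01:01	K562+A1	43
CTCFL	RSDEIVLTV	A*01:01	K562+A1	37
CTCFL	KLHGILVEA	A*02:01	K562+A2	12
CTCFL	DSKLAVSL	B*08:01	K562+B8	35
CTCFL	AETTGLIKL	B*40:01	COV362.4	51
CLDN6	GPSEYPTKNYV	A*01:01	EBV-9603+CLDN6	25
CLDN6	VLTSGIVFV	A*02:01	EBV-6519+CLDN6	23
CLDN6	DSKARLVL	B*08:01	EBV-9603+CLDN6	37
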
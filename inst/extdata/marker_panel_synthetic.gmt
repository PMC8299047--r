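PLASMA_DISEASE_MARKERS_SYNTHETIC	synthetic stand-in panel of approved plasma disease markers	ALB	SERPINA1	TF	HP	A2M	APOA1	APOB	C3	CRP	F2	FGA	FGB	FGG	PLG	TTR	B2M	CEACAM5	KLK3	AFP	MB	TNNI3	CGA	ERBB2	VWF	F8	SHBG	IGFBP3	TG	CALCA	PTH
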
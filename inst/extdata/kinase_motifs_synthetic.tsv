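motif	kinase
R-x-x-S#	PRKACA
R-x-x-S#	CAMK2A
R-x-R-x-x-S#	AKT1
S#-P	CDK1
S#-P	MAPK1
S#-P	MAPK3
T#-P	MAPK1
T#-P	CDK2
P-x-S#-P	MAPK1
P-x-S#-P	MAPK3
S#-x-x-E	CSNK2A1
S#-x-x-D	CSNK2A1
S#-Q	ATM
S#-Q	ATR
S#-x-x-x-S	GSK3B
K-x-x-S#	PKN1
R-x-x-T#	CAMK2A
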
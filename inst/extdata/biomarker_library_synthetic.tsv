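orf	gene	category	go_terms
YAR101W	HSP104	general	GO:0006950;GO:0009408
YAL102C	HSP12	general	GO:0006950;GO:0005737
YAR103C	HSP26	general	GO:0009408;GO:0005737
YAL104W	SSA1	general	GO:0006950;GO:0009408
YAR105W	SSA4	general	GO:0006950;GO:0005737
YAL106C	HSP78	general	GO:0009408;GO:0005737
YAR107C	HSP82	general	GO:0006950;GO:0009408
YAL108W	MSN2	general	GO:0006950;GO:0005737
YBR109W	MSN4	general	GO:0009408;GO:0005737
YBL110C	DDR48	general	GO:0006950;GO:0009408
YBR111C	TPS1	general	GO:0006950;GO:0005737
YBL112W	TPS2	general	GO:0009408;GO:0005737
YBR113W	HSP42	general	GO:0006950;GO:0009408
YBL114C	SIP18	general	GO:0006950;GO:0005737
YBR115C	PUN1	general	GO:0009408;GO:0005737
YBL116W	YCF1	chemical	GO:0042221;GO:0055085
YCR117W	SNQ2	chemical	GO:0042221;GO:0006749
YCL118C	ATM1	chemical	GO:0055085;GO:0005737
YCR119C	AQR1	chemical	GO:0042221;GO:0055085
YCL120W	ATR1	chemical	GO:0042221;GO:0006749
YCR121W	TPO1	chemical	GO:0055085;GO:0005737
YCL122C	PDR5	chemical	GO:0042221;GO:0055085
YCR123C	PDR15	chemical	GO:0042221;GO:0006749
YCL124W	FLR1	chemical	GO:0055085;GO:0005737
YDR125W	YOR1	chemical	GO:0042221;GO:0055085
YDL126C	GTT1	chemical	GO:0042221;GO:0006749
YDR127C	GTT2	chemical	GO:0055085;GO:0005737
YDL128W	GRE2	chemical	GO:0042221;GO:0055085
YDR129W	DDI1	chemical	GO:0042221;GO:0006749
YDL130C	CAD1	chemical	GO:0055085;GO:0005737
YDR131C	PHR1	DNA	GO:0006281;GO:0006974;GO:0005634
YDL132W	OGG1	DNA	GO:0006974;GO:0006259
YER133W	XRS2	DNA	GO:0006281;GO:0005634
YEL134C	MRE11	DNA	GO:0006259;GO:0007049
YER135C	RAD51	DNA	GO:0006281;GO:0006974;GO:0005634
YEL136W	RAD52	DNA	GO:0006974;GO:0006259
YER137W	RAD54	DNA	GO:0006281;GO:0005634
YEL138C	RAD18	DNA	GO:0006259;GO:0007049
YER139C	RNR2	DNA	GO:0006281;GO:0006974;GO:0005634
YEL140W	RNR4	DNA	GO:0006974;GO:0006259
YFR141W	DDR2	DNA	GO:0006281;GO:0005634
YFL142C	HUG1	DNA	GO:0006259;GO:0007049
YFR143C	MAG1	DNA	GO:0006281;GO:0006974;GO:0005634
YFL144W	APN1	DNA	GO:0006974;GO:0006259
YFR145W	DIN7	DNA	GO:0006281;GO:0005634
YFL146C	DUN1	DNA	GO:0006259;GO:0007049
YFR147C	SOD1	oxidative	GO:0006979;GO:0034599
YFL148W	SOD2	oxidative	GO:0006979;GO:0055114
YGR149W	CTT1	oxidative	GO:0034599;GO:0006749
YGL150C	CTA1	oxidative	GO:0006979;GO:0034599
YGR151C	TRX2	oxidative	GO:0006979;GO:0055114
YGL152W	TRR1	oxidative	GO:0034599;GO:0006749
YGR153W	GPX2	oxidative	GO:0006979;GO:0034599
YGL154C	GSH1	oxidative	GO:0006979;GO:0055114
YGR155C	GLR1	oxidative	GO:0034599;GO:0006749
YGL156W	AHP1	oxidative	GO:0006979;GO:0034599
YHR157W	TSA1	oxidative	GO:0006979;GO:0055114
YHL158C	PRX1	oxidative	GO:0034599;GO:0006749
YHR159C	YAP1	oxidative	GO:0006979;GO:0034599
YHL160W	GRX2	oxidative	GO:0006979;GO:0055114
YHR161W	UBI4	protein	GO:0006457;GO:0051603
YHL162C	UBC5	protein	GO:0006457;GO:0030433
YHR163C	PRE1	protein	GO:0051603;GO:0006807
YHL164W	PRE2	protein	GO:0006457;GO:0051603
YIR165W	PUP1	protein	GO:0006457;GO:0030433
YIL166C	RPN4	protein	GO:0051603;GO:0006807
YIR167C	HSP60	protein	GO:0006457;GO:0051603
YIL168W	HSP10	protein	GO:0006457;GO:0030433
YIR169W	KAR2	protein	GO:0051603;GO:0006807
YIL170C	PDI1	protein	GO:0006457;GO:0051603
YIR171C	ERO1	protein	GO:0006457;GO:0030433
YIL172W	IRE1	protein	GO:0051603;GO:0006807
YJR173W	LHS1	protein	GO:0006457;GO:0051603
YJL174C	SCJ1	protein	GO:0006457;GO:0030433
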
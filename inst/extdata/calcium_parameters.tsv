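parameter	baseline	units	description	genes	excluded_genes
gamma0	0.008	uM ms-1	Mean rate of plasma-membrane Ca2+ flux density	ATP2B1;ATP2B2;ATP2B4	ATP2B3
Vmax	0.1	uM ms-1	Amplitude of SERCA pump uptake	ATP2A1;ATP2A2;ATP2A3
gCaL	0.316	mS cm-1	L-type Ca2+ channel conductance	CACNA1C;CACNA1D;CACNA1S	CACNA1F
gCaT	0.1	mS cm-1	T-type Ca2+ channel conductance	CACNA1G;CACNA1H;CACNA1I
mGR0	0.0003	(fraction)	Metabotropic glutamate receptor density	GRM1;GRM5
k7	100	ms-1	G-alpha-bound activated PLC formation rate	GNAQ;GNA11;GNA14;GNA15
k9	0.83	ms-1	PLC-alpha-bound PIP2 formation rate	PLCB1;PLCB2;PLCB3;PLCB4;PLCD1;PLCD3;PLCD4;PLCE1;PLCG1;PLCG2;PLCZ1
gInsP3R	1.85	(dimensionless)	IP3 receptor density	ITPR1;ITPR2;ITPR3
PNMDA	1.938107025	nM s-1	Maximum NMDA receptor permeability	GRIN1;GRIN2A;GRIN2B;GRIN2C;GRIN2D;GRIN3A;GRIN3B
PAMPA	1.29207135	nM s-1	Maximum AMPA receptor permeability	GRIA1;GRIA2;GRIA4	GRIA3
gKA	22	mS cm-2	A-type K+ channel conductance	KCNA4;KCNC3;KCNC4;KCND2;KCND3	KCND1
gKDR	3	mS cm-2	Delayed rectifying K+ channel conductance	KCNA1;KCNA2;KCNA3;KCNA6;KCNA7;KCNB1;KCNB2;KCNC1;KCNC2
gNa	90	mS cm-2	Na+ channel conductance	SCN1A;SCN2A;SCN3A;SCN4A;SCN5A;SCN8A;SCN9A;SCN10A;SCN11A
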
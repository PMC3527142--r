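family	group	n_dm	n_am	dm_members
ASCa	A	4	2	ase,sc,lsc,ac
ASCb	A	0	0
MyoD	A	1	1	nau
E12/E47	A	1	1	da
Ngn	A	1	1	tap
NeuroD	A	0	0
Atonal	A	3	3	ato,cato,amos
Mist	A	1	2	Mistr
Beta3	A	1	1	Oli
Oligo	A	0	0
Net	A	1	1	net
Delilah	A	1	0	del
Mesp	A	1	1	sage
Twist	A	1	1	twi
Paraxis	A	1	1	Pxs
MyoRa	A	1	1	MyoR
MyoRb	A	0	0
Hand	A	1	1	Hand
PTFa	A	1	1	Fer1
PTFb	A	2	1	Fer2,Fer3
SCL	A	1	1	SCL
NSCL	A	1	1	NSCL
SRC	B	1	1	tai
Figa	B	0	0
Myc	B	1	1	dm
Mad	B	0	0
Mnt	B	1	1	Mnt
Max	B	1	1	Max
USF	B	1	2	USF
MITF	B	1	1	Mitf
SREBP	B	1	1	SREBP
AP4	B	1	1	crp
MLX	B	1	1	MLX
TF4	B	1	1	bmx
Clock	C	3	2	clk,clkB,clkC
ARNT	C	1	1	tgo
Bmal	C	1	1	cyc
AHR	C	2	2	dys,ss
Sim	C	1	1	sim
Trh	C	1	1	trh
HIF	C	1	1	sima
Emc	D	1	1	emc
Hey	E	2	2	Hey,Stich1
H/E(spl)	E	11	6	h,side,EsplmCd,Esplm3,EsplmBg,EsplmAb,Esplm7,Esplm5,Esplm8,EsplmG,EsplmD
COE	F	1	1	kn
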
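gene	family	group	contig	frame	start	end	intron_region	intron_length	note
PaAse1	ASCa	A	AEAC01008798.1	+3	9033	9242
PaAse2	ASCa	A	AEAC01008800.1	+2	11015	11191
PaDa	E12/E47	A	AEAC01014068.1	+3	28419	28447	basic	805
PaDa	E12/E47	A	AEAC01014068.1	+1	29253	29385
PaNau	MyoD	A	AEAC01019196.1	-2	74906	74862	helix1	1290
PaNau	MyoD	A	AEAC01019196.1	-2	73571	73461
PaTap(bp)	Ngn	A	AEAC01026729.1	-1	32156	31998
PaMistr1	Mist	A	AEAC01003460.1	-2	3518	3456	helix1	100
PaMistr1	Mist	A	AEAC01003460.1	-3	3355	3260
PaMistr2	Mist	A	AEAC01025732.1	-1	1835	1773	helix1	788
PaMistr2	Mist	A	AEAC01025732.1	-3	984	889
PaOli	Beta3	A	AEAC01025379.1	+2	21989	22153
PaCato	Atonal	A	AEAC01014266.1	-1	26350	26192
PaAto	Atonal	A	AEAC01015400.1	+2	188	346
PaAmos	Atonal	A	AEAC01014265.1	-1	11834	11676
PaNet	Net	A	AEAC01000094.1	+1	43	201
PaMyoR	MyoRa	A	AEAC01020981.1	-1	91681	91523
PaSage	Mesp	A	AEAC01024430.1	-2	277	116
PaPxs	Paraxis	A	AEAC01022136.1	+3	27672	27715	helix1	560
PaPxs	Paraxis	A	AEAC01022136.1	+2	28276	28390
PaTwi1	Twist	A	AEAC01021518.1	-3	26828	26673
PaTwi2	Twist	A	AEAC01021518.1	-3	48350	48195
PaFer1	PTFa	A	AEAC01026349.1	+1	45976	46134
PaFer2	PTFb	A	AEAC01016863.1	-3	13162	13119	helix1	410
PaFer2	PTFb	A	AEAC01016863.1	-2	12708	12594
PaFer3	PTFb	A	AEAC01022136.1	+2	110825	110905	helix1	2060
PaFer3	PTFb	A	AEAC01022136.1	+1	112966	113043
PaHand	Hand	A	AEAC01000415.1	+1	31600	31758
PaSCL	SCL	A	AEAC01013335.1	+2	41306	41445	helix2	769
PaSCL	SCL	A	AEAC01013335.1	+3	42215	42233
PaNSCL	NSCL	A	AEAC01011813.1	-1	35707	35685	basic	536
PaNSCL	NSCL	A	AEAC01011813.1	-3	35148	34998
PaMnt1	Mnt	B	AEAC01010687.1	+2	55730	55876	helix2	2123
PaMnt1	Mnt	B	AEAC01010687.1	+1	58000	58008
PaMnt2	Mnt	B	AEAC01009610.1	+1	110044	110202
PaMax1	Max	B	AEAC01023724.1	+3	2178	2336
PaMax2	Max	B	AEAC01012273.1	+1	1648	1803
PaDm	Myc	B	AEAC01001866.1	-3	39047	38889
PaUSF1	USF	B	AEAC01020973.1	-2	90699	90538	loop	88
PaUSF1	USF	B	AEAC01020973.1	-3	90449	90399
PaUSF2	USF	B	AEAC01025009.1	-1	32215	32075	loop	101
PaUSF2	USF	B	AEAC01025009.1	-3	31973	31923
PaMitf	MITF	B	AEAC01022111.1	+2	23396	23417	basic	5715
PaMitf	MITF	B	AEAC01022111.1	+2	29133	29208	loop	7943
PaMitf	MITF	B	AEAC01022111.1	+1	37152	37233
PaCrp1	AP4	B	AEAC01009287.1	+3	29454	29564			split
PaCrp1	AP4	B	AEAC01009292.1	+2	42008	42052			split
PaCrp2	AP4	B	AEAC01008415.1	+2	21659	21817
PaBmx	TF4	B	AEAC01010529.1	-1	64180	64010
PaMLX	MLX	B	AEAC01022037.1	-1	166446	166282
PaSREBP	SREBP	B	AEAC01008623.1	-2	34731	34589	helix2	82
PaSREBP	SREBP	B	AEAC01008623.1	-3	34506	34497
PaTai	SRC	B	AEAC01016429.1	-3	7000	6993	basic	2799
PaTai	SRC	B	AEAC01016429.1	-3	4193	4040
PaClk1	Clock	C	AEAC01024883.1	-3	2390	2386	basic	117
PaClk1	Clock	C	AEAC01024883.1	-3	2268	2121
PaClk2	Clock	C	AEAC01008322.1	+3	17766	17927
PaDys1	AHR	C	AEAC01000476.1	-3	12657	12496
PaDys2	AHR	C	AEAC01002106.1	-1	11804	11649
PaSs	AHR	C	AEAC01016399.1	+2	38537	38698
PaSim	Sim	C	AEAC01018973.1	+2	52010	52171
PaTrh	Trh	C	AEAC01014876.1	-3	10700	10539
PaSima	HIF	C	AEAC01025720.1	-1	31971	31810
PaTgo	ARNT	C	AEAC01022806.1	-1	23646	23485
PaCyc	Bmal	C	AEAC01003406.1	+3	16767	16771	basic	1814
PaCyc	Bmal	C	AEAC01003406.1	+2	18586	18742
PaEmc	Emc	D	AEAC01012314.1	+1	2998	3096
PaHey	Hey	E	AEAC01012628.1	+1	61852	62019
PaStich1	Hey	E	AEAC01002103.1	+3	5010	5177
PaH1	H/E(spl)	E	AEAC01020843.1	+1	70384	70389	basic	406
PaH1	H/E(spl)	E	AEAC01020843.1	+2	70796	70891	loop	272
PaH1	H/E(spl)	E	AEAC01020843.1	+1	71164	71235
PaH2	H/E(spl)	E	AEAC01020833.1	-2	8228	8223	basic	301
PaH2	H/E(spl)	E	AEAC01020833.1	-3	7921	7826	loop	3123
PaH2	H/E(spl)	E	AEAC01020833.1	-3	4702	4631
PaSide	H/E(spl)	E	AEAC01019264.1	-1	1124	957			split
PaSide	H/E(spl)	E	AEAC01019265.1	-2	1044	1039			split
PaE(spl)1	H/E(spl)	E	AEAC01003976.1	+1	4951	4956	basic	1338
PaE(spl)1	H/E(spl)	E	AEAC01003976.1	+1	6295	6384	loop	2233
PaE(spl)1	H/E(spl)	E	AEAC01003976.1	+2	8618	8695
PaE(spl)2	H/E(spl)	E	AEAC01003969.1	-2	11262	11257	basic	199
PaE(spl)2	H/E(spl)	E	AEAC01003969.1	-3	11057	10890
PaE(spl)3	H/E(spl)	E	AEAC01003972.1	+2	36986	37159
Pakn(col)	COE	F	AEAC01019320.1	-3	1427	1427	helix1	197
Pakn(col)	COE	F	AEAC01019320.1	-2	1229	1096
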
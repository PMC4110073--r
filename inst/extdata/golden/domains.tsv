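transcript_id	domain_id	start_aa	end_aa
G01.T1	G01.T1_D1	21	55
G02.T1	G02.T1_D1	5	32
G03.T1	G03.T1_D1	49	69
G03.T3	G03.T3_D1	7	19
G03.T4	G03.T4_D1	21	58
G04.T1	G04.T1_D1	173	188
G04.T2	G04.T2_D1	71	109
G04.T2	G04.T2_D2	16	40
G06.T1	G06.T1_D1	48	67
G06.T1	G06.T1_D2	66	75
G06.T2	G06.T2_D1	10	24
G07.T1	G07.T1_D1	54	91
G07.T1	G07.T1_D2	128	166
G10.T3	G10.T3_D1	46	85
G10.T3	G10.T3_D2	38	67
G11.T1	G11.T1_D1	118	133
G11.T1	G11.T1_D2	71	82
G11.T2	G11.T2_D1	81	94
G11.T2	G11.T2_D2	36	48
G12.T1	G12.T1_D1	119	139
G13.T1	G13.T1_D1	139	165
G14.T1	G14.T1_D1	41	63
G15.T1	G15.T1_D1	40	65
G15.T1	G15.T1_D2	21	47
G17.T1	G17.T1_D1	13	49
G17.T1	G17.T1_D2	7	33
G17.T2	G17.T2_D1	3	31
G17.T2	G17.T2_D2	5	20
G18.T1	G18.T1_D1	143	160
G18.T1	G18.T1_D2	36	50
G20.T2	G20.T2_D1	53	71
G20.T3	G20.T3_D1	29	52
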
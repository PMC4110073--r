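gene_id	transcript_id	chrom	strand	cds_starts	cds_ends	junction_cds	is_principal
G01	G01.T1	1	+	10000,10163,10541,10884,11137	10092,10276,10672,11003,11229	NA	1
G02	G02.T1	2	+	10000	10140	NA	1
G03	G03.T1	3	+	10000,10250,10643	10122,10378,10762	NA	1
G03	G03.T2	3	+	10250,10643	10378,10762	NA	0
G03	G03.T3	3	+	10250	10378	NA	0
G03	G03.T4	3	+	10000,10250	10122,10378	NA	0
G04	G04.T1	4	-	10000,10367,10728,10980,11340,11586	10119,10441,10811,11114,11474,11642	NA	0
G04	G04.T2	4	-	10000,10728,11340,11586	10119,10811,11474,11642	NA	0
G05	G05.T1	5	-	10000,10329,10476,10814,11178	10053,10391,10535,10888,11228	NA	0
G06	G06.T1	6	-	10000,10173,10550	10113,10295,10636	NA	1
G06	G06.T2	6	-	10173,10550	10295,10636	NA	0
G07	G07.T1	7	-	10000,10400,10537,10814,11060	10149,10450,10629,10924,11188	NA	1
G08	G08.T1	8	+	10000,10232,10651,10961,11375,11637	10083,10363,10725,11095,11461,11765	NA	0
G08	G08.T2	8	+	10651,11637	10725,11765	NA	0
G08	G08.T3	8	+	10000,10961	10083,11095	NA	1
G09	G09.T1	9	+	10000,10279,10575,10799,10962	10065,10365,10679,10846,11036	NA	1
G10	G10.T1	10	+	10000,10259,10655,10865	10143,10366,10741,10987	NA	0
G10	G10.T2	10	+	10000,10259,10655	10143,10366,10741	NA	0
G10	G10.T3	10	+	10000,10865	10143,10987	NA	0
G10	G10.T4	10	+	10259,10655,10865	10366,10741,10987	NA	1
G11	G11.T1	11	+	10000,10359,10606,10924,11184,11503	10104,10415,10746,10983,11231,11610	NA	1
G11	G11.T2	11	+	10000,10924,11184,11503	10104,10983,11231,11610	NA	0
G12	G12.T1	12	+	10000,10254,10587,10959,11198,11401	10080,10349,10724,11024,11332,11442	NA	1
G12	G12.T2	12	+	10000,10587,11198,11401	10080,10724,11332,11442	NA	0
G13	G13.T1	13	+	10000,10357,10646,10990,11282	10140,10467,10717,11085,11416	NA	1
G13	G13.T2	13	+	10000,10357,10646,10990	10140,10467,10717,11085	NA	0
G13	G13.T3	13	+	10646,10990,11282	10717,11085,11416	NA	0
G13	G13.T4	13	+	10000,10646,10990,11282	10140,10717,11085,11416	NA	0
G14	G14.T1	14	+	10000,10224,10503,10721,10891	10146,10325,10646,10792,10974	NA	1
G15	G15.T1	15	-	10000,10296	10101,10397	NA	1
G15	G15.T2	15	-	10296	10397	NA	0
G15	G15.T3	15	-	10000	10101	NA	0
G15	G15.T4	15	-	10296	10397	NA	0
G16	G16.T1	16	-	10000,10290,10606,10833,11022,11237	10068,10439,10683,10898,11090,11365	NA	1
G17	G17.T1	17	+	10000,10259,10437,10811	10047,10306,10535,10882	NA	0
G17	G17.T2	17	+	10000,10259,10811	10047,10306,10882	NA	0
G17	G17.T3	17	+	10000,10811	10047,10882	NA	0
G18	G18.T1	18	-	10000,10314,10584,10901,11185,11450	10122,10439,10664,10936,11298,11533	NA	0
G18	G18.T2	18	-	10000,10901	10122,10936	NA	1
G19	G19.T1	19	-	10000	10143	NA	1
G20	G20.T1	20	-	10000,10246,10407	10128,10287,10529	NA	1
G20	G20.T2	20	-	10000,10407	10128,10529	NA	0
G20	G20.T3	20	-	10000,10246	10128,10287	NA	0
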
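variant_id	label	class
V0001	1	pathogenic
V0002	1	pathogenic
V0003	1	pathogenic
V0004	1	pathogenic
V0005	1	pathogenic
V0006	1	pathogenic
V0007	1	pathogenic
V0008	1	pathogenic
V0009	1	pathogenic
V0010	1	pathogenic
V0011	1	pathogenic
V0012	1	pathogenic
V0013	1	pathogenic
V0014	1	pathogenic
V0015	1	pathogenic
V0016	1	pathogenic
V0017	1	pathogenic
V0018	1	pathogenic
V0019	1	pathogenic
V0020	1	pathogenic
V0021	1	pathogenic
V0022	1	pathogenic
V0023	1	pathogenic
V0024	1	pathogenic
V0025	1	pathogenic
V0026	1	pathogenic
V0027	1	pathogenic
V0028	1	pathogenic
V0029	1	pathogenic
V0030	1	pathogenic
V0031	1	pathogenic
V0032	1	pathogenic
V0033	1	pathogenic
V0034	1	pathogenic
V0035	1	pathogenic
V0036	1	pathogenic
V0037	1	pathogenic
V0038	1	pathogenic
V0039	1	pathogenic
V0040	1	pathogenic
V0041	1	pathogenic
V0042	1	pathogenic
V0043	1	pathogenic
V0044	1	pathogenic
V0045	1	pathogenic
V0046	1	pathogenic
V0047	1	pathogenic
V0048	1	pathogenic
V0049	1	pathogenic
V0050	1	pathogenic
V0051	1	pathogenic
V0052	1	pathogenic
V0053	1	pathogenic
V0054	1	pathogenic
V0055	1	pathogenic
V0056	1	pathogenic
V0057	1	pathogenic
V0058	1	pathogenic
V0059	1	pathogenic
V0060	1	pathogenic
V0061	1	pathogenic
V0062	1	pathogenic
V0063	1	pathogenic
V0064	1	pathogenic
V0065	1	pathogenic
V0066	1	pathogenic
V0067	1	pathogenic
V0068	1	pathogenic
V0069	1	pathogenic
V0070	1	pathogenic
V0071	1	pathogenic
V0072	1	pathogenic
V0073	1	pathogenic
V0074	1	pathogenic
V0075	1	pathogenic
V0076	1	pathogenic
V0077	1	pathogenic
V0078	1	pathogenic
V0079	1	pathogenic
V0080	1	pathogenic
V0081	1	pathogenic
V0082	1	pathogenic
V0083	1	pathogenic
V0084	1	pathogenic
V0085	1	pathogenic
V0086	1	pathogenic
V0087	1	pathogenic
V0088	1	pathogenic
V0089	1	pathogenic
V0090	1	pathogenic
V0091	1	pathogenic
V0092	1	pathogenic
V0093	1	pathogenic
V0094	1	pathogenic
V0095	1	pathogenic
V0096	1	pathogenic
V0097	1	pathogenic
V0098	1	pathogenic
V0099	1	pathogenic
V0100	1	pathogenic
V0101	0	benign
V0102	0	benign
V0103	0	benign
V0104	0	benign
V0105	0	benign
V0106	0	benign
V0107	0	benign
V0108	0	benign
V0109	0	benign
V0110	0	benign
V0111	0	benign
V0112	0	benign
V0113	0	benign
V0114	0	benign
V0115	0	benign
V0116	0	benign
V0117	0	benign
V0118	0	benign
V0119	0	benign
V0120	0	benign
V0121	0	benign
V0122	0	benign
V0123	0	benign
V0124	0	benign
V0125	0	benign
V0126	0	benign
V0127	0	benign
V0128	0	benign
V0129	0	benign
V0130	0	benign
V0131	0	benign
V0132	0	benign
V0133	0	benign
V0134	0	benign
V0135	0	benign
V0136	0	benign
V0137	0	benign
V0138	0	benign
V0139	0	benign
V0140	0	benign
V0141	0	benign
V0142	0	benign
V0143	0	benign
V0144	0	benign
V0145	0	benign
V0146	0	benign
V0147	0	benign
V0148	0	benign
V0149	0	benign
V0150	0	benign
V0151	0	benign
V0152	0	benign
V0153	0	benign
V0154	0	benign
V0155	0	benign
V0156	0	benign
V0157	0	benign
V0158	0	benign
V0159	0	benign
V0160	0	benign
V0161	0	benign
V0162	0	benign
V0163	0	benign
V0164	0	benign
V0165	0	benign
V0166	0	benign
V0167	0	benign
V0168	0	benign
V0169	0	benign
V0170	0	benign
V0171	0	benign
V0172	0	benign
V0173	0	benign
V0174	0	benign
V0175	0	benign
V0176	0	benign
V0177	0	benign
V0178	0	benign
V0179	0	benign
V0180	0	benign
V0181	0	benign
V0182	0	benign
V0183	0	benign
V0184	0	benign
V0185	0	benign
V0186	0	benign
V0187	0	benign
V0188	0	benign
V0189	0	benign
V0190	0	benign
V0191	0	benign
V0192	0	benign
V0193	0	benign
V0194	0	benign
V0195	0	benign
V0196	0	benign
V0197	0	benign
V0198	0	benign
V0199	0	benign
V0200	0	benign
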
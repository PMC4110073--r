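gene_id	transcript_id
G01	G01.T1
G02	G02.T1
G03	G03.T1
G06	G06.T1
G07	G07.T1
G08	G08.T3
G09	G09.T1
G10	G10.T4
G11	G11.T1
G12	G12.T1
G13	G13.T1
G14	G14.T1
G15	G15.T1
G16	G16.T1
G18	G18.T2
G19	G19.T1
G20	G20.T1
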
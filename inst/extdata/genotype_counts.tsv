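snp_id	control_major_hom	control_het	control_minor_hom	case_major_hom	case_het	case_minor_hom
rs1063147	379	140	12	544	224	21
rs7183308	479	52	0	702	85	2
rs17273206	323	183	25	463	280	46
rs7175811	277	212	42	401	314	74
rs3815003	274	214	43	383	335	71
rs6496724	263	212	56	361	337	91
rs4733220	190	240	101	282	391	116
rs2725361	227	239	65	312	364	113
rs2725338	290	199	42	448	291	50
rs1801195	227	232	72	311	363	115
rs2725383	422	101	8	594	175	20
rs1863280	326	179	26	474	281	34
rs11574311	428	94	9	575	192	22
rs4838519	135	269	127	208	367	214
rs4253038	247	236	48	359	339	91
rs2072668	195	246	90	308	362	119
rs2304277	184	248	99	295	370	124
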
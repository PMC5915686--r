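snp_id	control_major	control_minor	case_major	case_minor
rs1063147	898	164	1312	266
rs7183308	1010	52	1489	89
rs17273206	829	233	1206	372
rs8027126	978	84	1445	133
rs7175811	766	296	1116	462
rs3815003	762	300	1101	477
rs6496724	738	324	1059	519
rs4733220	620	442	955	623
rs2725361	693	369	988	590
rs2725338	779	283	1187	391
rs1801195	686	376	985	593
rs2725383	945	117	1363	215
rs1863280	831	231	1229	349
rs11574311	950	112	1342	236
rs4838519	539	523	801	777
rs4253038	730	332	1057	521
rs2072668	636	426	978	600
rs2304277	616	446	960	618
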
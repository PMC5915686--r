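snp_id	gene	major	minor
rs1063147	BLM	C	T
rs7183308	BLM	A	G
rs17273206	BLM	G	A
rs8027126	BLM	G	T
rs7175811	BLM	G	A
rs3815003	BLM	T	C
rs6496724	BLM	A	C
rs4733220	WRN	G	A
rs2725361	WRN	G	A
rs2725338	WRN	G	A
rs1801195	WRN	T	G
rs2725383	WRN	G	C
rs1863280	WRN	T	G
rs11574311	WRN	T	C
rs4838519	ERCC6	A	C
rs4253038	ERCC6	A	G
rs2072668	OGG1	G	C
rs2304277	OGG1	A	G
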
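triplet	query_chain	query_res	target_res
4G34	A	VAL606	ALA119
4G34	A	ALA619	VAL132
4G34	A	LYS621	LYS134
4G34	A	LEU642	PHE156
4G34	A	VAL651	VAL165
4G34	A	TYR653	TYR167
4G34	A	MET887	MET181
4G34	A	GLN888	GLU182
4G34	A	LEU889	TYR183
4G34	A	CYS890	ALA184
4G34	A	PHE943	PHE237
4G34	A	GLY953	GLY247
4G34	A	ASP954	ASP248
4G34	A	PHE955	PHE249
4BID	B	GLY687	GLY112
4BID	B	LYS688	GLN113
4BID	B	GLY689	GLY114
4BID	B	VAL694	ALA119
4BID	B	ALA707	VAL132
4BID	B	LYS709	LYS134
4BID	B	GLU725	GLU152
4BID	B	VAL738	VAL165
4BID	B	ILE752	ILE179
4BID	B	MET754	MET181
4BID	B	GLU755	GLU182
4BID	B	GLN756	TYR183
4BID	B	VAL757	ALA184
4BID	B	ASP807	ALA234
4BID	B	LEU810	PHE237
4BID	B	ASP822	ASP248
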
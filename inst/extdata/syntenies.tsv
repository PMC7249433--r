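gene	family	species	synteny	position
A1_x	x	spA	A1	1
A1_y	y	spA	A1	2
A1_z	z	spA	A1	3
A2_x	x	spA	A2	1
A2_z	z	spA	A2	2
B1_x	x	spB	B1	1
B1_y	y	spB	B1	2
B1_z	z	spB	B1	3
B2_x	x	spB	B2	1
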
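FAM1	I1	0	0	1	-9	A	A	G	T	0	0	A	A
FAM1	I2	0	0	2	-9	A	C	T	T	T	A	C	A
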
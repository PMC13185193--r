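1	m1	0.0001	100	A	C
1	m2	0.0002	200	G	T
2	m3	0.0001	150	T	A
2	m4	0.0004	400	C	A
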
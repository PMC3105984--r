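a	b	kind
A	B	F01
A	C	F01
A	D	F00
A	E	F01
A	F	F01
A	G	F01
B	E	SIM
C	D	F00
C	F	F01
C	G	F01
D	G	F11
F	G	F01
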
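element	case1	case2	case3	case4	case5	case6	case7	case8	case9	case10	case11	case12	case13
A	0	1	1	1	1	1	1	1	1	1	1	1	1
B	0	0	1	1	1	1	1	1	0	0	0	0	0
C	0	0	0	1	1	1	1	1	1	1	1	1	1
D	1	1	1	1	0	1	0	0	1	0	1	0	0
E	0	0	1	1	1	1	1	1	0	0	0	0	0
F	0	0	0	0	0	1	1	1	0	0	1	1	1
G	0	0	0	0	0	0	0	1	0	0	0	0	1
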
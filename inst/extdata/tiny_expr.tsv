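gene	s1	s2
HK1	1.5	2.5
LDHA	0	3
ACTB	4.25	1
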
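elem	radius
C	1.75
N	1.55
O	1.4
S	1.8
H	0.95
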
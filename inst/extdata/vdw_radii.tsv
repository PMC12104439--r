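atom_type	radius
H	1.17
H_polar	1.05
C	1.70
N	1.55
O	1.52
P	1.80
S	1.80
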
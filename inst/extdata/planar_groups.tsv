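res	group	atoms
ARG	guanidinium	CD,NE,CZ,NH1,NH2
ASN	amide	CB,CG,OD1,ND2
ASP	carboxylate	CB,CG,OD1,OD2
GLN	amide	CG,CD,OE1,NE2
GLU	carboxylate	CG,CD,OE1,OE2
HIS	imidazole	CB,CG,ND1,CD2,CE1,NE2
PHE	phenyl	CB,CG,CD1,CD2,CE1,CE2,CZ
TRP	indole	CB,CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2
TYR	phenol	CB,CG,CD1,CD2,CE1,CE2,CZ,OH
A	base	C1',N9,C8,N7,C5,C6,N6,N1,C2,N3,C4
G	base	C1',N9,C8,N7,C5,C6,O6,N1,C2,N2,N3,C4
C	base	C1',N1,C2,O2,N3,C4,N4,C5,C6
U	base	C1',N1,C2,O2,N3,C4,O4,C5,C6
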
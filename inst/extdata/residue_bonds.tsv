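res	atom1	atom2
ALA	N	CA
ALA	N	H
ALA	CA	C
ALA	CA	CB
ALA	CA	HA
ALA	C	O
ALA	CB	HB1
ALA	CB	HB2
ALA	CB	HB3
ARG	N	CA
ARG	N	H
ARG	CA	C
ARG	CA	CB
ARG	CA	HA
ARG	C	O
ARG	CB	CG
ARG	CB	HB2
ARG	CB	HB3
ARG	CG	CD
ARG	CG	HG2
ARG	CG	HG3
ARG	CD	NE
ARG	CD	HD2
ARG	CD	HD3
ARG	NE	CZ
ARG	NE	HE
ARG	CZ	NH1
ARG	CZ	NH2
ARG	NH1	HH11
ARG	NH1	HH12
ARG	NH2	HH21
ARG	NH2	HH22
ASN	N	CA
ASN	N	H
ASN	CA	C
ASN	CA	CB
ASN	CA	HA
ASN	C	O
ASN	CB	CG
ASN	CB	HB2
ASN	CB	HB3
ASN	CG	OD1
ASN	CG	ND2
ASN	ND2	HD21
ASN	ND2	HD22
ASP	N	CA
ASP	N	H
ASP	CA	C
ASP	CA	CB
ASP	CA	HA
ASP	C	O
ASP	CB	CG
ASP	CB	HB2
ASP	CB	HB3
ASP	CG	OD1
ASP	CG	OD2
ASP	OD2	HD2
CYS	N	CA
CYS	N	H
CYS	CA	C
CYS	CA	CB
CYS	CA	HA
CYS	C	O
CYS	CB	SG
CYS	CB	HB2
CYS	CB	HB3
CYS	SG	HG
GLN	N	CA
GLN	N	H
GLN	CA	C
GLN	CA	CB
GLN	CA	HA
GLN	C	O
GLN	CB	CG
GLN	CB	HB2
GLN	CB	HB3
GLN	CG	CD
GLN	CG	HG2
GLN	CG	HG3
GLN	CD	OE1
GLN	CD	NE2
GLN	NE2	HE21
GLN	NE2	HE22
GLU	N	CA
GLU	N	H
GLU	CA	C
GLU	CA	CB
GLU	CA	HA
GLU	C	O
GLU	CB	CG
GLU	CB	HB2
GLU	CB	HB3
GLU	CG	CD
GLU	CG	HG2
GLU	CG	HG3
GLU	CD	OE1
GLU	CD	OE2
GLU	OE2	HE2
GLY	N	CA
GLY	N	H
GLY	CA	C
GLY	CA	HA2
GLY	CA	HA3
GLY	C	O
HIS	N	CA
HIS	N	H
HIS	CA	C
HIS	CA	CB
HIS	CA	HA
HIS	C	O
HIS	CB	CG
HIS	CB	HB2
HIS	CB	HB3
HIS	CG	ND1
HIS	CG	CD2
HIS	ND1	CE1
HIS	ND1	HD1
HIS	CD2	NE2
HIS	CD2	HD2
HIS	CE1	NE2
HIS	CE1	HE1
HIS	NE2	HE2
ILE	N	CA
ILE	N	H
ILE	CA	C
ILE	CA	CB
ILE	CA	HA
ILE	C	O
ILE	CB	CG1
ILE	CB	CG2
ILE	CB	HB
ILE	CG1	CD1
ILE	CG1	HG12
ILE	CG1	HG13
ILE	CG2	HG21
ILE	CG2	HG22
ILE	CG2	HG23
ILE	CD1	HD11
ILE	CD1	HD12
ILE	CD1	HD13
LEU	N	CA
LEU	N	H
LEU	CA	C
LEU	CA	CB
LEU	CA	HA
LEU	C	O
LEU	CB	CG
LEU	CB	HB2
LEU	CB	HB3
LEU	CG	CD1
LEU	CG	CD2
LEU	CG	HG
LEU	CD1	HD11
LEU	CD1	HD12
LEU	CD1	HD13
LEU	CD2	HD21
LEU	CD2	HD22
LEU	CD2	HD23
LYS	N	CA
LYS	N	H
LYS	CA	C
LYS	CA	CB
LYS	CA	HA
LYS	C	O
LYS	CB	CG
LYS	CB	HB2
LYS	CB	HB3
LYS	CG	CD
LYS	CG	HG2
LYS	CG	HG3
LYS	CD	CE
LYS	CD	HD2
LYS	CD	HD3
LYS	CE	NZ
LYS	CE	HE2
LYS	CE	HE3
LYS	NZ	HZ1
LYS	NZ	HZ2
LYS	NZ	HZ3
MET	N	CA
MET	N	H
MET	CA	C
MET	CA	CB
MET	CA	HA
MET	C	O
MET	CB	CG
MET	CB	HB2
MET	CB	HB3
MET	CG	SD
MET	CG	HG2
MET	CG	HG3
MET	SD	CE
MET	CE	HE1
MET	CE	HE2
MET	CE	HE3
PHE	N	CA
PHE	N	H
PHE	CA	C
PHE	CA	CB
PHE	CA	HA
PHE	C	O
PHE	CB	CG
PHE	CB	HB2
PHE	CB	HB3
PHE	CG	CD1
PHE	CG	CD2
PHE	CD1	CE1
PHE	CD1	HD1
PHE	CD2	CE2
PHE	CD2	HD2
PHE	CE1	CZ
PHE	CE1	HE1
PHE	CE2	CZ
PHE	CE2	HE2
PHE	CZ	HZ
PRO	N	CA
PRO	N	CD
PRO	N	H
PRO	CA	C
PRO	CA	CB
PRO	CA	HA
PRO	C	O
PRO	CB	CG
PRO	CB	HB2
PRO	CB	HB3
PRO	CG	CD
PRO	CG	HG2
PRO	CG	HG3
PRO	CD	HD2
PRO	CD	HD3
SER	N	CA
SER	N	H
SER	CA	C
SER	CA	CB
SER	CA	HA
SER	C	O
SER	CB	OG
SER	CB	HB2
SER	CB	HB3
SER	OG	HG
THR	N	CA
THR	N	H
THR	CA	C
THR	CA	CB
THR	CA	HA
THR	C	O
THR	CB	OG1
THR	CB	CG2
THR	CB	HB
THR	OG1	HG1
THR	CG2	HG21
THR	CG2	HG22
THR	CG2	HG23
TRP	N	CA
TRP	N	H
TRP	CA	C
TRP	CA	CB
TRP	CA	HA
TRP	C	O
TRP	CB	CG
TRP	CB	HB2
TRP	CB	HB3
TRP	CG	CD1
TRP	CG	CD2
TRP	CD1	NE1
TRP	CD1	HD1
TRP	CD2	CE2
TRP	CD2	CE3
TRP	NE1	CE2
TRP	NE1	HE1
TRP	CE2	CZ2
TRP	CE3	CZ3
TRP	CE3	HE3
TRP	CZ2	CH2
TRP	CZ2	HZ2
TRP	CZ3	CH2
TRP	CZ3	HZ3
TRP	CH2	HH2
TYR	N	CA
TYR	N	H
TYR	CA	C
TYR	CA	CB
TYR	CA	HA
TYR	C	O
TYR	CB	CG
TYR	CB	HB2
TYR	CB	HB3
TYR	CG	CD1
TYR	CG	CD2
TYR	CD1	CE1
TYR	CD1	HD1
TYR	CD2	CE2
TYR	CD2	HD2
TYR	CE1	CZ
TYR	CE1	HE1
TYR	CE2	CZ
TYR	CE2	HE2
TYR	CZ	OH
TYR	OH	HH
VAL	N	CA
VAL	N	H
VAL	CA	C
VAL	CA	CB
VAL	CA	HA
VAL	C	O
VAL	CB	CG1
VAL	CB	CG2
VAL	CB	HB
VAL	CG1	HG11
VAL	CG1	HG12
VAL	CG1	HG13
VAL	CG2	HG21
VAL	CG2	HG22
VAL	CG2	HG23
A	P	OP1
A	P	OP2
A	P	O5'
A	O5'	C5'
A	C5'	C4'
A	C5'	H5'
A	C5'	H5''
A	C4'	O4'
A	C4'	C3'
A	C4'	H4'
A	O4'	C1'
A	C3'	O3'
A	C3'	C2'
A	C3'	H3'
A	C2'	O2'
A	C2'	C1'
A	C2'	H2'
A	O2'	HO2'
A	C1'	N9
A	C1'	H1'
A	N9	C8
A	N9	C4
A	C8	N7
A	C8	H8
A	N7	C5
A	C5	C6
A	C5	C4
A	C6	N6
A	C6	N1
A	N6	H61
A	N6	H62
A	N1	C2
A	C2	N3
A	N3	C4
C	P	OP1
C	P	OP2
C	P	O5'
C	O5'	C5'
C	C5'	C4'
C	C5'	H5'
C	C5'	H5''
C	C4'	O4'
C	C4'	C3'
C	C4'	H4'
C	O4'	C1'
C	C3'	O3'
C	C3'	C2'
C	C3'	H3'
C	C2'	O2'
C	C2'	C1'
C	C2'	H2'
C	O2'	HO2'
C	C1'	N1
C	C1'	H1'
C	N1	C2
C	N1	C6
C	C2	O2
C	C2	N3
C	N3	C4
C	C4	N4
C	C4	C5
C	N4	H41
C	N4	H42
C	C5	C6
C	C5	H5
C	C6	H6
G	P	OP1
G	P	OP2
G	P	O5'
G	O5'	C5'
G	C5'	C4'
G	C5'	H5'
G	C5'	H5''
G	C4'	O4'
G	C4'	C3'
G	C4'	H4'
G	O4'	C1'
G	C3'	O3'
G	C3'	C2'
G	C3'	H3'
G	C2'	O2'
G	C2'	C1'
G	C2'	H2'
G	O2'	HO2'
G	C1'	N9
G	C1'	H1'
G	N9	C8
G	N9	C4
G	C8	N7
G	C8	H8
G	N7	C5
G	C5	C6
G	C5	C4
G	C6	O6
G	C6	N1
G	N1	C2
G	N1	H1
G	C2	N2
G	C2	N3
G	N2	H21
G	N2	H22
G	N3	C4
U	P	OP1
U	P	OP2
U	P	O5'
U	O5'	C5'
U	C5'	C4'
U	C5'	H5'
U	C5'	H5''
U	C4'	O4'
U	C4'	C3'
U	C4'	H4'
U	O4'	C1'
U	C3'	O3'
U	C3'	C2'
U	C3'	H3'
U	C2'	O2'
U	C2'	C1'
U	C2'	H2'
U	O2'	HO2'
U	C1'	N1
U	C1'	H1'
U	N1	C2
U	N1	C6
U	C2	O2
U	C2	N3
U	N3	C4
U	N3	H3
U	C4	O4
U	C4	C5
U	C5	C6
U	C5	H5
U	C6	H6
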
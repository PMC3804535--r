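res	atom	a1	a2	a3	bond	ang	tors	ttype	elem
ALA	CB	C	N	CA	1.53	110.5	122.6	fix	C
SER	CB	C	N	CA	1.53	110.5	122.6	fix	C
SER	OG	N	CA	CB	1.417	110.8	0	chi1	O
SER	HG	CA	CB	OG	0.96	109.5	0	chi2	H
CYS	CB	C	N	CA	1.53	110.5	122.6	fix	C
CYS	SG	N	CA	CB	1.808	113.8	0	chi1	S
CYS	HG	CA	CB	SG	1.33	96	0	chi2	H
THR	CB	C	N	CA	1.53	110.5	122.6	fix	C
THR	OG1	N	CA	CB	1.433	109.6	0	chi1	O
THR	CG2	N	CA	CB	1.521	110.5	-120	chi1	C
THR	HG1	CA	CB	OG1	0.96	109.5	0	chi2	H
VAL	CB	C	N	CA	1.53	110.5	122.6	fix	C
VAL	CG1	N	CA	CB	1.521	110.5	0	chi1	C
VAL	CG2	N	CA	CB	1.521	110.5	122	chi1	C
LEU	CB	C	N	CA	1.53	110.5	122.6	fix	C
LEU	CG	N	CA	CB	1.53	116.3	0	chi1	C
LEU	CD1	CA	CB	CG	1.521	110.7	0	chi2	C
LEU	CD2	CA	CB	CG	1.521	110.7	122	chi2	C
ILE	CB	C	N	CA	1.53	110.5	122.6	fix	C
ILE	CG1	N	CA	CB	1.53	110.4	0	chi1	C
ILE	CG2	N	CA	CB	1.521	110.5	-122	chi1	C
ILE	CD1	CA	CB	CG1	1.513	113.8	0	chi2	C
MET	CB	C	N	CA	1.53	110.5	122.6	fix	C
MET	CG	N	CA	CB	1.52	114.1	0	chi1	C
MET	SD	CA	CB	CG	1.803	112.7	0	chi2	S
MET	CE	CB	CG	SD	1.791	100.9	0	chi3	C
PRO	CB	C	N	CA	1.53	110.5	122.6	fix	C
PRO	CG	N	CA	CB	1.492	104.5	25	fix	C
PRO	CD	CA	CB	CG	1.503	106.1	-35	fix	C
ASP	CB	C	N	CA	1.53	110.5	122.6	fix	C
ASP	CG	N	CA	CB	1.516	112.6	0	chi1	C
ASP	OD1	CA	CB	CG	1.249	118.4	0	chi2	O
ASP	OD2	CA	CB	CG	1.249	118.4	180	chi2	O
ASN	CB	C	N	CA	1.53	110.5	122.6	fix	C
ASN	CG	N	CA	CB	1.516	112.6	0	chi1	C
ASN	OD1	CA	CB	CG	1.231	120.8	0	chi2	O
ASN	ND2	CA	CB	CG	1.328	116.4	180	chi2	N
ASN	HD21	CB	CG	ND2	1.01	120	0	fix	H
ASN	HD22	CB	CG	ND2	1.01	120	180	fix	H
GLU	CB	C	N	CA	1.53	110.5	122.6	fix	C
GLU	CG	N	CA	CB	1.52	114.1	0	chi1	C
GLU	CD	CA	CB	CG	1.516	112.6	0	chi2	C
GLU	OE1	CB	CG	CD	1.249	118.4	0	chi3	O
GLU	OE2	CB	CG	CD	1.249	118.4	180	chi3	O
GLN	CB	C	N	CA	1.53	110.5	122.6	fix	C
GLN	CG	N	CA	CB	1.52	114.1	0	chi1	C
GLN	CD	CA	CB	CG	1.516	112.6	0	chi2	C
GLN	OE1	CB	CG	CD	1.231	120.8	0	chi3	O
GLN	NE2	CB	CG	CD	1.328	116.4	180	chi3	N
GLN	HE21	CG	CD	NE2	1.01	120	0	fix	H
GLN	HE22	CG	CD	NE2	1.01	120	180	fix	H
LYS	CB	C	N	CA	1.53	110.5	122.6	fix	C
LYS	CG	N	CA	CB	1.52	114.1	0	chi1	C
LYS	CD	CA	CB	CG	1.52	111.3	0	chi2	C
LYS	CE	CB	CG	CD	1.52	111.3	0	chi3	C
LYS	NZ	CG	CD	CE	1.489	111.9	0	chi4	N
LYS	HZ1	CD	CE	NZ	1.01	109.5	180	fix	H
LYS	HZ2	CD	CE	NZ	1.01	109.5	60	fix	H
LYS	HZ3	CD	CE	NZ	1.01	109.5	-60	fix	H
ARG	CB	C	N	CA	1.53	110.5	122.6	fix	C
ARG	CG	N	CA	CB	1.52	114.1	0	chi1	C
ARG	CD	CA	CB	CG	1.52	111.3	0	chi2	C
ARG	NE	CB	CG	CD	1.46	112	0	chi3	N
ARG	CZ	CG	CD	NE	1.329	124.2	0	chi4	C
ARG	NH1	CD	NE	CZ	1.326	120	0	fix	N
ARG	NH2	CD	NE	CZ	1.326	120	180	fix	N
ARG	HE	NH1	CZ	NE	1.01	118	180	fix	H
ARG	HH11	NE	CZ	NH1	1.01	120	0	fix	H
ARG	HH12	NE	CZ	NH1	1.01	120	180	fix	H
ARG	HH21	NE	CZ	NH2	1.01	120	0	fix	H
ARG	HH22	NE	CZ	NH2	1.01	120	180	fix	H
HIS	CB	C	N	CA	1.53	110.5	122.6	fix	C
HIS	CG	N	CA	CB	1.497	113.8	0	chi1	C
HIS	ND1	CA	CB	CG	1.371	122.7	0	chi2	N
HIS	CD2	CA	CB	CG	1.356	129.1	180	chi2	C
HIS	CE1	CB	CG	ND1	1.319	109	180	fix	C
HIS	NE2	CB	CG	CD2	1.374	107.2	180	fix	N
HIS	HE2	CG	CD2	NE2	1.01	125	180	fix	H
PHE	CB	C	N	CA	1.53	110.5	122.6	fix	C
PHE	CG	N	CA	CB	1.502	113.8	0	chi1	C
PHE	CD1	CA	CB	CG	1.39	120.8	0	chi2	C
PHE	CD2	CA	CB	CG	1.39	120.8	180	chi2	C
PHE	CE1	CB	CG	CD1	1.39	120	180	fix	C
PHE	CE2	CB	CG	CD2	1.39	120	180	fix	C
PHE	CZ	CG	CD1	CE1	1.39	120	0	fix	C
TYR	CB	C	N	CA	1.53	110.5	122.6	fix	C
TYR	CG	N	CA	CB	1.502	113.8	0	chi1	C
TYR	CD1	CA	CB	CG	1.39	120.8	0	chi2	C
TYR	CD2	CA	CB	CG	1.39	120.8	180	chi2	C
TYR	CE1	CB	CG	CD1	1.39	120	180	fix	C
TYR	CE2	CB	CG	CD2	1.39	120	180	fix	C
TYR	CZ	CG	CD1	CE1	1.39	120	0	fix	C
TYR	OH	CD1	CE1	CZ	1.376	119.9	180	fix	O
TYR	HH	CE1	CZ	OH	0.96	109.5	180	fix	H
TRP	CB	C	N	CA	1.53	110.5	122.6	fix	C
TRP	CG	N	CA	CB	1.498	113.6	0	chi1	C
TRP	CD1	CA	CB	CG	1.365	126.9	0	chi2	C
TRP	CD2	CA	CB	CG	1.433	126.6	180	chi2	C
TRP	NE1	CD2	CG	CD1	1.374	110.2	0	fix	N
TRP	CE2	CD1	CG	CD2	1.409	107.2	0	fix	C
TRP	CE3	CD1	CG	CD2	1.4	133.9	180	fix	C
TRP	CZ2	CG	CD2	CE2	1.4	122.4	180	fix	C
TRP	CZ3	CG	CD2	CE3	1.39	118.6	180	fix	C
TRP	CH2	CD2	CE2	CZ2	1.37	117.5	0	fix	C
TRP	HE1	CG	CD1	NE1	1.01	125	180	fix	H
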
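res	chi1	chi2	chi3	chi4	sigma
SER	-60	-60	NA	NA	10
SER	60	-60	NA	NA	10
SER	180	-60	NA	NA	10
SER	-60	60	NA	NA	10
SER	60	60	NA	NA	10
SER	180	60	NA	NA	10
SER	-60	180	NA	NA	10
SER	60	180	NA	NA	10
SER	180	180	NA	NA	10
CYS	-60	-60	NA	NA	10
CYS	60	-60	NA	NA	10
CYS	180	-60	NA	NA	10
CYS	-60	60	NA	NA	10
CYS	60	60	NA	NA	10
CYS	180	60	NA	NA	10
CYS	-60	180	NA	NA	10
CYS	60	180	NA	NA	10
CYS	180	180	NA	NA	10
THR	-60	-60	NA	NA	10
THR	60	-60	NA	NA	10
THR	180	-60	NA	NA	10
THR	-60	60	NA	NA	10
THR	60	60	NA	NA	10
THR	180	60	NA	NA	10
THR	-60	180	NA	NA	10
THR	60	180	NA	NA	10
THR	180	180	NA	NA	10
VAL	-60	NA	NA	NA	10
VAL	60	NA	NA	NA	10
VAL	180	NA	NA	NA	10
LEU	-60	-60	NA	NA	10
LEU	60	-60	NA	NA	10
LEU	180	-60	NA	NA	10
LEU	-60	60	NA	NA	10
LEU	60	60	NA	NA	10
LEU	180	60	NA	NA	10
LEU	-60	180	NA	NA	10
LEU	60	180	NA	NA	10
LEU	180	180	NA	NA	10
ILE	-60	-60	NA	NA	10
ILE	60	-60	NA	NA	10
ILE	180	-60	NA	NA	10
ILE	-60	60	NA	NA	10
ILE	60	60	NA	NA	10
ILE	180	60	NA	NA	10
ILE	-60	180	NA	NA	10
ILE	60	180	NA	NA	10
ILE	180	180	NA	NA	10
MET	-60	-60	180	NA	10
MET	60	-60	180	NA	10
MET	180	-60	180	NA	10
MET	-60	60	180	NA	10
MET	60	60	180	NA	10
MET	180	60	180	NA	10
MET	-60	180	180	NA	10
MET	60	180	180	NA	10
MET	180	180	180	NA	10
ASP	-60	-60	NA	NA	10
ASP	60	-60	NA	NA	10
ASP	180	-60	NA	NA	10
ASP	-60	60	NA	NA	10
ASP	60	60	NA	NA	10
ASP	180	60	NA	NA	10
ASP	-60	180	NA	NA	10
ASP	60	180	NA	NA	10
ASP	180	180	NA	NA	10
ASN	-60	-60	NA	NA	10
ASN	60	-60	NA	NA	10
ASN	180	-60	NA	NA	10
ASN	-60	60	NA	NA	10
ASN	60	60	NA	NA	10
ASN	180	60	NA	NA	10
ASN	-60	180	NA	NA	10
ASN	60	180	NA	NA	10
ASN	180	180	NA	NA	10
GLU	-60	-60	180	NA	10
GLU	60	-60	180	NA	10
GLU	180	-60	180	NA	10
GLU	-60	60	180	NA	10
GLU	60	60	180	NA	10
GLU	180	60	180	NA	10
GLU	-60	180	180	NA	10
GLU	60	180	180	NA	10
GLU	180	180	180	NA	10
GLN	-60	-60	180	NA	10
GLN	60	-60	180	NA	10
GLN	180	-60	180	NA	10
GLN	-60	60	180	NA	10
GLN	60	60	180	NA	10
GLN	180	60	180	NA	10
GLN	-60	180	180	NA	10
GLN	60	180	180	NA	10
GLN	180	180	180	NA	10
LYS	-60	-60	180	180	10
LYS	60	-60	180	180	10
LYS	180	-60	180	180	10
LYS	-60	60	180	180	10
LYS	60	60	180	180	10
LYS	180	60	180	180	10
LYS	-60	180	180	180	10
LYS	60	180	180	180	10
LYS	180	180	180	180	10
ARG	-60	-60	180	180	10
ARG	60	-60	180	180	10
ARG	180	-60	180	180	10
ARG	-60	60	180	180	10
ARG	60	60	180	180	10
ARG	180	60	180	180	10
ARG	-60	180	180	180	10
ARG	60	180	180	180	10
ARG	180	180	180	180	10
HIS	-60	-90	NA	NA	10
HIS	60	-90	NA	NA	10
HIS	180	-90	NA	NA	10
HIS	-60	90	NA	NA	10
HIS	60	90	NA	NA	10
HIS	180	90	NA	NA	10
PHE	-60	-90	NA	NA	10
PHE	60	-90	NA	NA	10
PHE	180	-90	NA	NA	10
PHE	-60	90	NA	NA	10
PHE	60	90	NA	NA	10
PHE	180	90	NA	NA	10
TYR	-60	-90	NA	NA	10
TYR	60	-90	NA	NA	10
TYR	180	-90	NA	NA	10
TYR	-60	90	NA	NA	10
TYR	60	90	NA	NA	10
TYR	180	90	NA	NA	10
TRP	-60	-90	NA	NA	10
TRP	60	-90	NA	NA	10
TRP	180	-90	NA	NA	10
TRP	-60	90	NA	NA	10
TRP	60	90	NA	NA	10
TRP	180	90	NA	NA	10
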
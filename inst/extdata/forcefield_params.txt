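# Reduced protein force-field parameter table.
# Heavy-atom backbone (N, CA, C, O) and CB partial charges for the 20
# standard amino acids, with element-level Lennard-Jones parameters and
# van der Waals radii. Charges in elementary charge units; epsilon in
# kcal/mol; sigma and radii in Angstrom. User-replaceable: pass an
# alternative file to read_forcefield().
#
# [charges]: residue atom charge
[charges]
ALA  N    -0.470
ALA  CA    0.070
ALA  C     0.510
ALA  O    -0.510
ALA  CB    0.000
ARG  N    -0.470
ARG  CA    0.070
ARG  C     0.510
ARG  O    -0.510
ARG  CB    0.000
ASN  N    -0.470
ASN  CA    0.070
ASN  C     0.510
ASN  O    -0.510
ASN  CB    0.000
ASP  N    -0.470
ASP  CA    0.070
ASP  C     0.510
ASP  O    -0.510
ASP  CB    0.000
CYS  N    -0.470
CYS  CA    0.070
CYS  C     0.510
CYS  O    -0.510
CYS  CB    0.000
GLN  N    -0.470
GLN  CA    0.070
GLN  C     0.510
GLN  O    -0.510
GLN  CB    0.000
GLU  N    -0.470
GLU  CA    0.070
GLU  C     0.510
GLU  O    -0.510
GLU  CB    0.000
GLY  N    -0.470
GLY  CA    0.070
GLY  C     0.510
GLY  O    -0.510
HIS  N    -0.470
HIS  CA    0.070
HIS  C     0.510
HIS  O    -0.510
HIS  CB    0.000
ILE  N    -0.470
ILE  CA    0.070
ILE  C     0.510
ILE  O    -0.510
ILE  CB    0.000
LEU  N    -0.470
LEU  CA    0.070
LEU  C     0.510
LEU  O    -0.510
LEU  CB    0.000
LYS  N    -0.470
LYS  CA    0.070
LYS  C     0.510
LYS  O    -0.510
LYS  CB    0.000
MET  N    -0.470
MET  CA    0.070
MET  C     0.510
MET  O    -0.510
MET  CB    0.000
PHE  N    -0.470
PHE  CA    0.070
PHE  C     0.510
PHE  O    -0.510
PHE  CB    0.000
PRO  N    -0.470
PRO  CA    0.070
PRO  C     0.510
PRO  O    -0.510
PRO  CB    0.000
SER  N    -0.470
SER  CA    0.070
SER  C     0.510
SER  O    -0.510
SER  CB    0.000
THR  N    -0.470
THR  CA    0.070
THR  C     0.510
THR  O    -0.510
THR  CB    0.000
TRP  N    -0.470
TRP  CA    0.070
TRP  C     0.510
TRP  O    -0.510
TRP  CB    0.000
TYR  N    -0.470
TYR  CA    0.070
TYR  C     0.510
TYR  O    -0.510
TYR  CB    0.000
VAL  N    -0.470
VAL  CA    0.070
VAL  C     0.510
VAL  O    -0.510
VAL  CB    0.000

# [lj]: element epsilon sigma
[lj]
C 0.10 3.40
N 0.17 3.25
O 0.21 2.96
S 0.25 3.56

# [radii]: element vdw_radius
[radii]
C 1.70
N 1.55
O 1.52
S 1.80
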
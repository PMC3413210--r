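resname,atom1,atom2,ideal,sigma,link
*,N,CA,1.458,0.019,0
*,CA,C,1.525,0.021,0
*,C,O,1.231,0.020,0
*,C,OXT,1.249,0.019,0
*,CA,CB,1.530,0.020,0
*,C,N,1.329,0.014,1
GLY,N,CA,1.451,0.016,0
GLY,CA,C,1.516,0.018,0
PRO,N,CA,1.466,0.015,0
PRO,N,CD,1.473,0.014,0
ALA,CA,CB,1.521,0.033,0
THR,CA,CB,1.542,0.027,0
VAL,CA,CB,1.540,0.027,0
ILE,CA,CB,1.540,0.027,0
SER,CB,OG,1.417,0.020,0
THR,CB,OG1,1.433,0.016,0
THR,CB,CG2,1.521,0.033,0
CYS,CB,SG,1.808,0.033,0
VAL,CB,CG1,1.521,0.033,0
VAL,CB,CG2,1.521,0.033,0
ILE,CB,CG1,1.530,0.020,0
ILE,CB,CG2,1.521,0.033,0
ILE,CG1,CD1,1.513,0.039,0
LEU,CB,CG,1.530,0.020,0
LEU,CG,CD1,1.521,0.033,0
LEU,CG,CD2,1.521,0.033,0
MET,CB,CG,1.520,0.030,0
MET,CG,SD,1.803,0.034,0
MET,SD,CE,1.791,0.059,0
LYS,CB,CG,1.520,0.030,0
LYS,CG,CD,1.520,0.030,0
LYS,CD,CE,1.520,0.030,0
LYS,CE,NZ,1.489,0.030,0
ARG,CB,CG,1.520,0.030,0
ARG,CG,CD,1.520,0.030,0
ARG,CD,NE,1.460,0.018,0
ARG,NE,CZ,1.329,0.014,0
ARG,CZ,NH1,1.326,0.018,0
ARG,CZ,NH2,1.326,0.018,0
ASP,CB,CG,1.516,0.025,0
ASP,CG,OD1,1.249,0.019,0
ASP,CG,OD2,1.249,0.019,0
ASN,CB,CG,1.516,0.025,0
ASN,CG,OD1,1.231,0.019,0
ASN,CG,ND2,1.328,0.021,0
GLU,CB,CG,1.520,0.030,0
GLU,CG,CD,1.516,0.025,0
GLU,CD,OE1,1.249,0.019,0
GLU,CD,OE2,1.249,0.019,0
GLN,CB,CG,1.520,0.030,0
GLN,CG,CD,1.516,0.025,0
GLN,CD,OE1,1.231,0.019,0
GLN,CD,NE2,1.328,0.021,0
HIS,CB,CG,1.497,0.014,0
HIS,CG,ND1,1.378,0.011,0
HIS,ND1,CE1,1.321,0.010,0
HIS,CE1,NE2,1.321,0.010,0
HIS,NE2,CD2,1.374,0.011,0
HIS,CG,CD2,1.354,0.011,0
PHE,CB,CG,1.502,0.023,0
PHE,CG,CD1,1.384,0.021,0
PHE,CG,CD2,1.384,0.021,0
PHE,CD1,CE1,1.384,0.021,0
PHE,CD2,CE2,1.384,0.021,0
PHE,CE1,CZ,1.384,0.021,0
PHE,CE2,CZ,1.384,0.021,0
TYR,CB,CG,1.512,0.022,0
TYR,CG,CD1,1.384,0.021,0
TYR,CG,CD2,1.384,0.021,0
TYR,CD1,CE1,1.384,0.021,0
TYR,CD2,CE2,1.384,0.021,0
TYR,CE1,CZ,1.384,0.021,0
TYR,CE2,CZ,1.384,0.021,0
TYR,CZ,OH,1.376,0.021,0
TRP,CB,CG,1.498,0.031,0
TRP,CG,CD1,1.365,0.025,0
TRP,CG,CD2,1.433,0.018,0
TRP,CD1,NE1,1.374,0.021,0
TRP,NE1,CE2,1.370,0.011,0
TRP,CE2,CD2,1.409,0.017,0
TRP,CD2,CE3,1.398,0.016,0
TRP,CE3,CZ3,1.382,0.030,0
TRP,CZ3,CH2,1.400,0.025,0
TRP,CH2,CZ2,1.368,0.019,0
TRP,CZ2,CE2,1.394,0.021,0
PRO,CB,CG,1.492,0.050,0
PRO,CG,CD,1.503,0.034,0
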
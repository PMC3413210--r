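resname,atom1,atom2,atom3,ideal,sigma,link
*,N,CA,C,111.2,2.8,0
*,CA,C,O,120.8,1.7,0
*,CA,C,OXT,117.0,2.0,0
*,N,CA,CB,110.5,1.7,0
*,CA,C,N,116.2,2.0,1
*,O,C,N,123.0,1.6,1
*,C,N,CA,121.7,1.8,1
GLY,N,CA,C,112.5,2.9,0
PRO,C,N,CA,122.6,5.0,1
PRO,C,N,CD,125.0,4.1,1
PRO,CA,N,CD,112.0,1.4,0
PRO,N,CA,CB,103.0,1.1,0
SER,CA,CB,OG,111.1,2.0,0
CYS,CA,CB,SG,114.4,2.3,0
THR,CA,CB,OG1,109.6,1.5,0
THR,CA,CB,CG2,110.5,1.7,0
VAL,CA,CB,CG1,110.5,1.7,0
VAL,CA,CB,CG2,110.5,1.7,0
ILE,CA,CB,CG1,110.4,1.7,0
ILE,CA,CB,CG2,110.5,1.7,0
ILE,CB,CG1,CD1,113.8,2.1,0
LEU,CA,CB,CG,116.3,3.5,0
LEU,CB,CG,CD1,110.7,3.0,0
LEU,CB,CG,CD2,110.7,3.0,0
MET,CA,CB,CG,114.1,2.0,0
MET,CB,CG,SD,112.7,3.0,0
MET,CG,SD,CE,100.9,2.2,0
LYS,CA,CB,CG,114.1,2.0,0
LYS,CB,CG,CD,111.3,2.3,0
LYS,CG,CD,CE,111.3,2.3,0
LYS,CD,CE,NZ,111.9,3.2,0
ARG,CA,CB,CG,114.1,2.0,0
ARG,CB,CG,CD,111.3,2.3,0
ARG,CG,CD,NE,112.0,2.2,0
ARG,CD,NE,CZ,124.2,1.5,0
ARG,NE,CZ,NH1,120.0,1.9,0
ARG,NE,CZ,NH2,120.0,1.9,0
ASP,CA,CB,CG,112.6,1.0,0
ASP,CB,CG,OD1,118.4,2.3,0
ASP,CB,CG,OD2,118.4,2.3,0
ASN,CA,CB,CG,112.6,1.0,0
ASN,CB,CG,OD1,120.8,2.0,0
ASN,CB,CG,ND2,116.4,1.5,0
GLU,CA,CB,CG,114.1,2.0,0
GLU,CB,CG,CD,112.6,1.7,0
GLU,CG,CD,OE1,118.4,2.3,0
GLU,CG,CD,OE2,118.4,2.3,0
GLN,CA,CB,CG,114.1,2.0,0
GLN,CB,CG,CD,112.6,1.7,0
GLN,CG,CD,OE1,120.8,2.0,0
GLN,CG,CD,NE2,116.4,1.5,0
HIS,CA,CB,CG,113.8,1.0,0
HIS,CB,CG,ND1,122.7,1.5,0
HIS,CG,ND1,CE1,105.7,1.0,0
HIS,ND1,CE1,NE2,111.5,1.3,0
HIS,CE1,NE2,CD2,107.3,1.0,0
PHE,CA,CB,CG,113.8,1.0,0
PHE,CB,CG,CD1,120.7,1.7,0
PHE,CG,CD1,CE1,120.0,1.5,0
PHE,CD1,CE1,CZ,120.0,1.5,0
PHE,CE1,CZ,CE2,120.0,1.8,0
PHE,CZ,CE2,CD2,120.0,1.5,0
TYR,CA,CB,CG,113.9,1.0,0
TYR,CB,CG,CD1,120.8,1.5,0
TYR,CG,CD1,CE1,120.0,1.5,0
TYR,CD1,CE1,CZ,120.0,1.5,0
TYR,CE1,CZ,CE2,120.0,1.8,0
TYR,CZ,CE2,CD2,120.0,1.5,0
TYR,CE1,CZ,OH,120.0,2.4,0
TRP,CA,CB,CG,113.6,1.6,0
TRP,CB,CG,CD1,126.9,1.5,0
TRP,CG,CD1,NE1,110.2,1.0,0
TRP,CD1,NE1,CE2,108.9,1.0,0
TRP,NE1,CE2,CD2,107.4,1.0,0
TRP,CE2,CD2,CE3,118.8,1.0,0
TRP,CD2,CE3,CZ3,118.6,1.0,0
TRP,CE3,CZ3,CH2,121.1,1.0,0
TRP,CZ3,CH2,CZ2,121.5,1.0,0
PRO,CA,CB,CG,104.5,1.9,0
PRO,CB,CG,CD,106.1,3.2,0
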
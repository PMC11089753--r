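residue,steric,hydrophobicity,volume,polarisability,isoelectric_point,helix_prob,sheet_prob
ALA,1.28,0.31,1.00,0.05,6.11,0.42,0.23
ARG,2.34,-1.01,6.13,0.29,10.74,0.36,0.25
ASN,1.60,-0.60,2.95,0.13,6.52,0.21,0.22
ASP,1.60,-0.77,2.78,0.11,2.95,0.25,0.20
CYS,1.77,1.54,2.43,0.13,6.35,0.17,0.41
GLN,1.56,-0.22,3.95,0.18,5.65,0.36,0.25
GLU,1.56,-0.64,3.78,0.15,3.09,0.42,0.21
GLY,0.00,0.00,0.00,0.00,6.07,0.13,0.15
HIS,2.99,0.13,4.66,0.23,7.69,0.27,0.30
ILE,4.19,1.80,4.00,0.19,6.04,0.30,0.45
LEU,2.59,1.70,4.00,0.19,6.04,0.39,0.31
LYS,1.89,-0.99,4.77,0.22,9.99,0.32,0.27
MET,2.35,1.23,4.43,0.22,5.71,0.38,0.32
PHE,2.94,1.79,5.89,0.29,5.67,0.30,0.38
PRO,2.67,0.72,2.72,0.00,6.80,0.13,0.34
SER,1.31,-0.04,1.60,0.06,5.70,0.20,0.28
THR,3.03,0.26,2.60,0.11,5.60,0.21,0.36
TRP,3.21,2.25,8.08,0.41,5.94,0.32,0.42
TYR,2.94,0.96,6.47,0.30,5.66,0.25,0.41
VAL,3.67,1.22,3.00,0.14,6.02,0.27,0.49
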
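# Default amino-acid classification at neutral pH.
# group: exactly one primary category per residue (negative, positive, polar, hydrophobic)
# aromatic: flag; aromatic residues are additionally counted inside the hydrophobic group
# HIS is treated as neutral/polar at pH 7.
resname	group	aromatic
ALA	hydrophobic	FALSE
ARG	positive	FALSE
ASN	polar	FALSE
ASP	negative	FALSE
CYS	polar	FALSE
GLN	polar	FALSE
GLU	negative	FALSE
GLY	hydrophobic	FALSE
HIS	polar	FALSE
ILE	hydrophobic	FALSE
LEU	hydrophobic	FALSE
LYS	positive	FALSE
MET	hydrophobic	FALSE
PHE	hydrophobic	TRUE
PRO	hydrophobic	FALSE
SER	polar	FALSE
THR	polar	FALSE
TRP	hydrophobic	TRUE
TYR	hydrophobic	TRUE
VAL	hydrophobic	FALSE
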
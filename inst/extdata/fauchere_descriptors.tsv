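# Side-chain physiochemical descriptors for the 20 standard amino acids.
# HB: hydrophobicity, water-octanol partition scale (Fauchere & Pliska side-chain analogues)
# PB: polarizability (dimensionless)
# GSI: graph shape index (dimensionless)
# nVdW: normalized van der Waals volume (dimensionless)
# Source: Fauchere et al., Int J Pept Protein Res 32:269-278 (1988); AAindex FAUJ880 entries.
resname	HB	PB	GSI	nVdW
ALA	0.31	0.046	1.28	1.00
ARG	-1.01	0.291	2.34	6.13
ASN	-0.60	0.134	1.60	2.95
ASP	-0.77	0.105	1.60	2.78
CYS	1.54	0.128	1.77	2.43
GLN	-0.22	0.180	1.56	3.95
GLU	-0.64	0.151	1.56	3.78
GLY	0.00	0.000	0.00	0.00
HIS	0.13	0.230	2.99	4.66
ILE	1.80	0.186	4.19	4.00
LEU	1.70	0.186	2.59	4.00
LYS	-0.99	0.219	1.89	4.77
MET	1.23	0.221	2.35	4.43
PHE	1.79	0.290	2.94	5.89
PRO	0.72	0.131	2.67	2.72
SER	-0.04	0.062	1.31	1.60
THR	0.26	0.108	3.03	2.60
TRP	2.25	0.409	3.21	8.08
TYR	0.96	0.298	2.94	6.47
VAL	1.22	0.140	3.67	3.00
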
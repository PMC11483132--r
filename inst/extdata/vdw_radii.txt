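# Van der Waals radii by element symbol (Angstrom).
# Single-element set after Bondi (1964) with Mantina et al. (2009)
# extensions; one row per element: SYMBOL<TAB>RADIUS
H	1.10
D	1.10
C	1.70
N	1.55
O	1.52
S	1.80
P	1.80
SE	1.90
F	1.47
CL	1.75
BR	1.83
I	1.98
ZN	2.10
FE	2.05
MG	1.73
CA	2.31
NA	2.27
K	2.75
MN	2.05
CU	2.00
CO	2.00
NI	1.97
CD	2.18
HG	2.05
LI	1.82
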
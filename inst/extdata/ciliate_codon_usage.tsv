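amino_acid	codon	T_pyriformis	P_caudatum	P_tetraurelia
A	GCG	0.03	0.03	0.08
A	GCA	0.32	0.41	0.20
A	GCT	0.57	0.54	0.30
A	GCC	0.07	0.02	0.41
C	TGT	0.86	0.85	0.24
C	TGC	0.14	0.15	0.76
D	GAT	0.81	0.81	0.36
D	GAC	0.19	0.19	0.64
E	GAG	0.08	0.17	0.70
E	GAA	0.92	0.83	0.30
F	TTT	0.89	0.95	0.62
F	TTC	0.11	0.05	0.38
G	GGG	0.03	0.05	0.27
G	GGA	0.16	0.19	0.20
G	GGT	0.78	0.73	0.16
G	GGC	0.03	0.04	0.37
H	CAT	0.69	0.69	0.31
H	CAC	0.31	0.31	0.69
I	ATA	0.62	0.42	0.21
I	ATT	0.33	0.53	0.33
I	ATC	0.06	0.05	0.46
K	AAG	0.04	0.11	0.64
K	AAA	0.96	0.89	0.36
L	TTG	0.03	0.09	0.13
L	TTA	0.75	0.74	0.14
L	CTG	0.01	0.01	0.09
L	CTA	0.13	0.05	0.15
L	CTT	0.07	0.11	0.19
L	CTC	0.01	0.01	0.31
M	ATG	1.00	1.00	1.00
N	AAT	0.79	0.77	0.34
N	AAC	0.21	0.23	0.66
P	CCG	0.07	0.03	0.03
P	CCA	0.36	0.42	0.16
P	CCT	0.54	0.51	0.27
P	CCC	0.03	0.04	0.54
Q	CAG	0.06	0.14	0.58
Q	CAA	0.94	0.86	0.42
R	AGG	0.02	0.17	0.45
R	AGA	0.95	0.74	0.16
R	CGG	0.00	0.00	0.03
R	CGA	0.00	0.02	0.11
R	CGT	0.02	0.06	0.06
R	CGC	0.00	0.01	0.18
S	AGT	0.21	0.24	0.07
S	AGC	0.06	0.09	0.27
S	TCG	0.03	0.03	0.12
S	TCA	0.32	0.20	0.10
S	TCT	0.34	0.42	0.24
S	TCC	0.04	0.03	0.20
T	ACG	0.01	0.03	0.22
T	ACA	0.53	0.45	0.18
T	ACT	0.41	0.49	0.23
T	ACC	0.06	0.03	0.37
V	GTG	0.04	0.06	0.19
V	GTA	0.49	0.35	0.20
V	GTT	0.42	0.55	0.30
V	GTC	0.06	0.04	0.31
W	TGG	0.03	0.01	0.48
W	TGA	0.97	0.99	0.52
Y	TAT	0.82	0.79	0.38
Y	TAC	0.18	0.21	0.62
Stop	TAG	0.00	0.00	0.39
Stop	TAA	1.00	1.00	0.61
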
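# Chou-Fasman secondary-structure propensities (x100): P(alpha) and P(beta).
# Chou & Fasman (1978) Annu Rev Biochem 47:251-276.
residue	p_helix	p_strand
A	142	83
C	70	119
D	101	54
E	151	37
F	113	138
G	57	75
H	100	87
I	108	160
K	114	74
L	121	130
M	145	105
N	67	89
P	57	55
Q	111	110
R	98	93
S	77	75
T	83	119
V	106	170
W	108	137
Y	69	147
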
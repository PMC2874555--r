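residue	value
A	10.04
R	6.18
N	5.63
D	5.76
C	8.89
Q	5.41
E	5.37
G	7.99
H	7.49
I	8.72
L	8.79
K	4.4
M	9.15
F	7.98
P	7.79
S	7.08
T	7
W	8.07
Y	6.9
V	8.88
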
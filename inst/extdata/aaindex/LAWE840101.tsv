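residue	value
A	-0.48
R	-0.06
N	-0.87
D	-0.75
C	-0.32
Q	-0.32
E	-0.71
G	0
H	-0.51
I	0.81
L	1.02
K	-0.09
M	0.81
F	1.03
P	2.03
S	0.05
T	-0.35
W	0.66
Y	1.24
V	0.56
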
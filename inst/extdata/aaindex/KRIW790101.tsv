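residue	value
A	4.32
R	6.55
N	6.24
D	6.04
C	1.73
Q	6.13
E	6.17
G	6.09
H	5.66
I	2.31
L	3.93
K	7.92
M	2.44
F	2.59
P	7.19
S	5.37
T	5.16
W	2.78
Y	3.58
V	3.31
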
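residue	value
A	4.55
R	5.97
N	5.56
D	2.85
C	-0.78
Q	4.15
E	5.16
G	9.14
H	4.48
I	2.1
L	3.24
K	10.68
M	2.18
F	4.37
P	5.14
S	6.78
T	8.6
W	1.97
Y	2.4
V	3.81
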
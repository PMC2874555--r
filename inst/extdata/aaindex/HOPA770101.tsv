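residue	value
A	1
R	2.3
N	2.2
D	6.5
C	0.1
Q	2.1
E	6.2
G	1.1
H	2.8
I	0.8
L	0.8
K	5.3
M	0.7
F	1.4
P	0.9
S	1.7
T	1.5
W	1.9
Y	2.1
V	0.9
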
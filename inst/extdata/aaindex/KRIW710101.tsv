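residue	value
A	4.6
R	6.5
N	5.9
D	5.7
C	-1
Q	6.1
E	5.6
G	7.6
H	4.5
I	2.6
L	3.25
K	7.9
M	1.4
F	3.2
P	7
S	5.25
T	4.8
W	4
Y	4.35
V	3.4
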
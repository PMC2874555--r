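residue	value
A	0.28
R	0.34
N	0.31
D	0.33
C	0.11
Q	0.39
E	0.37
G	0.28
H	0.23
I	0.12
L	0.16
K	0.59
M	0.08
F	0.1
P	0.46
S	0.27
T	0.26
W	0.15
Y	0.25
V	0.22
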
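residue	value
A	-0.2
R	-0.12
N	0.08
D	-0.2
C	-0.45
Q	0.16
E	-0.3
G	0
H	-0.12
I	-2.26
L	-2.46
K	-0.35
M	-1.47
F	-2.33
P	-0.98
S	-0.39
T	-0.52
W	-2.01
Y	-2.24
V	-1.56
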
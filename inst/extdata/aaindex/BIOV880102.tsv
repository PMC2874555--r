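residue	value
A	44
R	-68
N	-72
D	-91
C	90
Q	-117
E	-139
G	-8
H	47
I	100
L	108
K	-188
M	121
F	148
P	-36
S	-60
T	-54
W	163
Y	22
V	117
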
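residue	value
A	16
R	-70
N	-74
D	-78
C	168
Q	-73
E	-106
G	-13
H	50
I	151
L	145
K	-141
M	124
F	189
P	-20
S	-70
T	-38
W	145
Y	53
V	123
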
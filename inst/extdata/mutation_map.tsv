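from_residue	to_residue
G	L
A	L
V	L
L	V
I	V
F	L
M	L
P	L
W	L
S	T
C	S
T	S
Y	S
H	S
K	R
R	K
Q	N
N	Q
D	E
E	D
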
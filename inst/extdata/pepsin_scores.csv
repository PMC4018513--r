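residue,p1_score,p1prime_score
G,0,0
A,0,0
S,0,0
P,-4,-4
V,0,0
T,0,0
C,0,0
L,2,0
I,0,0
N,0,0
D,0,0
Q,0,0
K,-4,0
E,0,0
M,2,0
H,-4,0
F,2,0
R,-4,0
Y,2,0
W,2,0
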
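# Synthetic stand-in for the classic 34-symbol SMILES fingerprint alphabet
# (the historical list is not reprinted here; this reconstruction covers the
# organic subset, halogens, brackets, bonds, charges, ring digits and '%').
# One symbol per line; two-character symbols are matched greedily.
C
c
N
n
O
o
S
s
P
F
I
B
Cl
Br
(
)
[
]
=
#
-
+
H
0
1
2
3
4
5
6
7
8
9
%
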
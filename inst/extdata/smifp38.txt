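# Extended 38-symbol fingerprint alphabet: the 34-symbol set minus '%' plus
# the chirality ('@', '@@'), component ('.') and directional-bond tokens.
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
@
@@
.
\
/
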
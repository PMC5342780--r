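label	direction
G12	conserved
T20	conserved
Q22	conserved
F28	conserved
Y32	conserved
D33	conserved
P34	conserved
T35	conserved
I36	conserved
D54	conserved
T58	conserved
A59	conserved
G60	conserved
Y64	conserved
A66	conserved
R68	conserved
Y71	conserved
G77	conserved
V103	conserved
I139	variable
E153	conserved
C186	conserved
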
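haplogroup	marker	parent
C-M130	M130	ROOT
C2-M217	M217	M130
C2-M48	M48	M217
C2-M407	M407	M217
D-M174	M174	ROOT
E1b1b-M35.1	M35.1	ROOT
E1b1b1a-M78	M78	M35.1
E1b1b1b-M123	M123	M35.1
G1-M285	M285	ROOT
G2-P15	P15	ROOT
H-M69	M69	ROOT
I-M170	M170	ROOT
I1-M253	M253	M170
I2a-P37.2	P37.2	M170
J1-M267	M267	ROOT
J1a-P58	P58	M267
J2-M172	M172	ROOT
J2a1-M47	M47	M172
J2a2-M67	M67	M172
J2a2a-M92	M92	M67
J2b-M12	M12	M172
L-M20	M20	ROOT
N-M231	M231	ROOT
N1a1a-M178	M178	M231
O-M175	M175	ROOT
O1a-M119	M119	M175
O2-M122	M122	M175
O2a-M134	M134	M122
Q-M242	M242	ROOT
R-M207	M207	ROOT
R1a1a-M198	M198	M207
R1b-M343	M343	M207
R1b1a-M269	M269	M343
R2-M124	M124	M207
T-M70	M70	ROOT
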
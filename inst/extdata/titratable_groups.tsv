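name	pattern	tag
carboxylic_acid	[CX3](=O)[OX2H1]	acidic
phenol	[c][OX2H1]	acidic
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3;H1,H2]	acidic
thiol	[SX2H1]	acidic
carbon_acid	[CX4;H1,H2]([CX3]=[OX1])[CX3]=[OX1]	acidic
tetrazole	c1nnn[nH]1	acidic
aliphatic_amine	[NX3;H2,H1,H0;!$(NC=[O,S,N]);!$(N=*);!$(N[a])&!a]	basic
basic_aromatic_n	[nX2;!$([nX2][#8])]	basic
amidine_guanidine	[NX3][CX3]=[NX2]	basic
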
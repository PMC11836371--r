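# Coupling reaction templates for building-block library enumeration.
# name<TAB>SMIRKS ; application is a graph rewrite equivalent to the SMIRKS.
amide_coupling	[CX3:1](=[OX1:2])[OX2H].[NX3;H2,H1;!$([NX3][CX3]=[OX1]):3]>>[CX3:1](=[OX1:2])[NX3:3]
suzuki_coupling	[c:1][Cl,Br,I].[c:2][BX3]([OX2H])[OX2H]>>[c:1][c:2]
chan_lam_amination	[c:1][BX3]([OX2H])[OX2H].[NX3;H2,H1;!$([NX3][CX3]=[OX1]):2]>>[c:1][NX3:2]
ullmann_ether	[c:1][Cl,Br,I].[OX2H1:2]>>[c:1][OX2:2]
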
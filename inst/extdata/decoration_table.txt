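# Decoration transformations applied after heteroatom mutation.
# name<TAB>SMIRKS ; editable, but names must stay in the registered set.
carboxylic_to_sulfonic	[CX3:1](=[OX1:2])[OX2H:3]>>[S:1](=[O:2])(=O)[OH:3]
phenol_to_F	[c:1][OX2H]>>[c:1]F
phenol_to_Cl	[c:1][OX2H]>>[c:1]Cl
phenol_to_Br	[c:1][OX2H]>>[c:1]Br
phenol_to_I	[c:1][OX2H]>>[c:1]I
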
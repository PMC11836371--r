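# Representative subset of pan-assay interference (PAINS) motifs, written
# as SMARTS for this package. This is NOT the full published catalog; runs
# record this file's version in their manifest because pass/fail counts
# depend on the list. version: growspace-pains-subset-1
catechol	[OX2H]c1ccccc1[OX2H]
hydroquinone	[OX2H]c1ccc([OX2H])cc1
para_quinone	O=C1C=CC(=O)C=C1
ortho_quinone	O=C1C(=O)C=CC=C1
rhodanine	S=C1[NX3]C(=O)CS1
thiazolidinone	O=C1[NX3]C(=S)SC1
azo_aryl	c[NX2]=[NX2]c
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=[CX3]
ene_one_dione	O=[CX3]C(=[CX3])[CX3]=O
hydroxyphenyl_hydrazone	[OX2H]c1ccccc1[CX3]=[NX2][NX3]
mannich_phenol	[OX2H]c1ccccc1[CH2][NX3]
nitro_styrene	[O-,O]=[N+](~[O-,O])C=Cc1ccccc1
isothiazolone	O=C1C=CS[NX3]1
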
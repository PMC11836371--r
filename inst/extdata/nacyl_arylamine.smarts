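# Exclusion filter: N-acylated six-membered arylamines.
# Removes the chemotype class dominating the target pocket so that novel
# scaffolds are not crowded out of the top ranks.
nacyl_arylamine	[cr6][NX3][CX3]=[OX1]
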
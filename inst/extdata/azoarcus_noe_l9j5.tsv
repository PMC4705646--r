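# L9/J5 restraint roster: S-bead NOEs docking the L9 tetraloop onto the
# J5 receptor.
type	a	b
noe	A181	U53
noe	A181	A72
noe	A183	C52
noe	A183	G74
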
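# Triple-helix (TH) restraint roster: S-bead NOEs docking J3/4 onto P6
# and J6/7 onto P4, plus the two backbone dihedrals separating P4 and P6
# (bead-space quadruples chosen by the implementer and documented here).
type	a	b
noe	A39	C87
noe	A39	G113
noe	A40	C86
noe	A40	G114
noe	G116	C43
noe	G116	G83
noe	U117	G44
noe	U117	C82
dih	P85 S85 P86 S86	
dih	S85 P86 S86 P87	
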
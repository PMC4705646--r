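# Azoarcus group I ribozyme fixture (synthetic transcription):
# architecture reconstructed from the published secondary-structure map and
# the residue anchors printed in the methods (restraint rosters, loop and
# joiner identities); pair-level detail away from those anchors is the
# implementer's reconstruction, not a verbatim copy of any figure.
# sequence: GUAAGGCCAGCGAAAGCUGGCAAGCACAAGACGGCAAGGCCUAUGCGACUUCGGUCGCAUAAGGCCCAGCCGUCCCGAAAGCAGCCUAACUAGCUGCAUUCGGAGUGGCAGAAUGUGCGCGUCCCUAGCAGAAAUCUGCUAUGGGACGCAAUAACCUGCCAAAGGCACGAAAGUGCCUAAUGCCAGUUAACUGGC
# numbering: 12 206
i	j	class
17	32	canonical
18	31	canonical
19	30	canonical
20	29	canonical
21	28	canonical
22	27	canonical
35	129	canonical
36	128	canonical
37	127	canonical
38	126	canonical
41	85	canonical
42	84	canonical
43	83	canonical
44	82	canonical
45	81	canonical
46	80	canonical
49	77	canonical
50	76	canonical
51	75	canonical
52	74	noncanonical
55	70	noncanonical
56	69	canonical
57	68	canonical
58	67	canonical
59	66	canonical
60	65	canonical
86	114	canonical
87	113	canonical
88	112	canonical
89	111	canonical
90	110	noncanonical
92	108	canonical
93	107	canonical
94	106	canonical
95	105	canonical
96	104	canonical
118	171	canonical
119	170	canonical
120	169	canonical
121	168	canonical
122	167	canonical
130	160	canonical
131	159	canonical
132	158	canonical
133	157	canonical
134	156	canonical
135	155	noncanonical
138	151	noncanonical
139	150	canonical
140	149	canonical
141	148	canonical
142	147	canonical
174	189	canonical
175	188	canonical
176	187	canonical
177	186	canonical
178	185	canonical
179	184	canonical
193	206	canonical
194	205	canonical
195	204	canonical
196	203	canonical
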
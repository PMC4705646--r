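# Tethered tetraloop/tetraloop-receptor reference system:
# GAAA tetraloop hairpin joined by an oligo-U tether to an 11-nt-receptor
# hairpin (residues 26-50, held restrained during production runs).
# sequence: GGCAGCGAAAGCUGCCUUUUUUUUUGCGACCCUGAGAAACUCAUGGUCGC
# numbering: 1 50
i	j	class
1	16	canonical
2	15	canonical
3	14	canonical
4	13	canonical
5	12	canonical
6	11	canonical
26	50	canonical
27	49	canonical
28	48	canonical
29	47	canonical
30	46	canonical
31	45	noncanonical
33	43	noncanonical
34	42	canonical
35	41	canonical
36	40	canonical
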
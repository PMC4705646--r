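# Region rosters for the Azoarcus fixture (crystal numbering;
# synthetic transcription, see azoarcus_pairs.tsv). For helices the first
# range is the Euler-frame reference strand.
# numbering: 12 206
name	positions
5ploop	12-16
P2	17-22,27-32
L2	23-26
J2/3	33-34
P3	35-38,126-129
J3/4	39-40
P4	41-46,80-85
J4/5	47-48
P5	49-51,75-77
J5	52-55,70-74
P5b	56-60,65-69
L5	61-64
J5/4	78-79
P6	86-89,111-114
P6il	90-91,109-110
P6a	92-96,104-108
L6	97-103
J6/7	115-117
P7	118-122,167-171
J7/3	123-125
P8	130-134,156-160
J8	135-138,151-155
P8b	139-142,147-150
L8	143-146
J8/7	161-166
J7/9	172-173
P9	174-179,184-189
L9	180-183
J9/9A	190-192
P9A	193-196,203-206
L9A	197-202
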
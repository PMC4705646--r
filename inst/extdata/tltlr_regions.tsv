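# Regions of the TL/TLR reference system.
# numbering: 1 50
name	positions
TLstem	1-6,11-16
TL	7-10
tether	17-25
TLRstem	26-30,46-50
TLR	31-33,43-45
TLRinner	34-36,40-42
TLRloop	37-39
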
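# Synthetic default pattern set (editable; one pattern per line:
# name<TAB>spec<TAB>key_positions).
# CoRNR is the CoRNR-box consensus; SHARP is an illustrative synthetic
# stand-in for the C-terminal SHARP-interaction motif, whose published
# consensus is not redistributed here.
CoRNR	L/I.x.x.I/H.I.x.x.x.I/L
SHARP	G.P.S/T.L/I.x.x.L
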
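trait	grand_mean
DM	143.45
SW	18.43
SY	20.82
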
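model	trait	deviance	lrt_vs_full
no_progeny	DM	7048.74	141.17
no_progeny	SW	2398.04	94.15
no_progeny	SY	5837.97	15.68
no_gxe	DM	7010.14	102.57
no_gxe	SW	2362.57	58.68
no_gxe	SY	5853.38	31.09
full	DM	6907.57	NA
full	SW	2303.89	NA
full	SY	5822.29	NA
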
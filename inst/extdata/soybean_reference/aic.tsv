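model	trait	full	reduced_no_prog	reduced_no_int
FMTME	DM,SW,SY	14861.22	15184.53	15051.87
FSTME	DM	6913.569	7052.743	7014.143
FSTME	SW	2309.892	2402.042	2366.568
FSTME	SY	5828.291	5841.969	5857.377
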
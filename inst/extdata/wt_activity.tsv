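strain	replicate	deltaA_per_min
WT	1	0.0111
WT	2	0.0108
WT	3	0.0114
dCutF	1	0.0011
dCutF	2	0.0010
dCutF	3	0.0012
dCutO	1	0
dCutO	2	0
dCutO	3	0
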
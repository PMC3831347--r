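name	super_class	weight	use_in_bias	q_lower.T1	q_upper.T1	q_lower.T2	q_upper.T2
Air	Background	1	FALSE	0	0.1	0	0.1
Csf	CSF	1	TRUE	0	0.6	0.2	1
Gm	GM	1	TRUE	0.04	0.9	0.05	0.95
Wm	WM	1	TRUE	0.5	1	0	0.7
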
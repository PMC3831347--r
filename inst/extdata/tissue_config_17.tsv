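name	super_class	weight	use_in_bias	q_lower.T1	q_upper.T1	q_lower.T2	q_upper.T2
Accumben	GM	1	FALSE	0.05	0.95	0.15	0.97
Caudate	GM	1	FALSE	0.05	0.95	0.15	0.97
Crbl Gm	GM	1	TRUE	0.03	0.9	0.02	0.99
Hippocampus	GM	1	FALSE	0.05	0.95	0.15	0.97
Putamen	GM	1	FALSE	0.05	0.95	0.15	0.97
Surf Gm	GM	1	TRUE	0.04	0.75	0.25	0.96
Wm	WM	1	TRUE	0.5	1	0.05	0.7
Crbl Wm	WM	1.5	TRUE	0.1	1	0.03	0.9
Csf	CSF	1	TRUE	0	0.6	0.2	1
Thalamus	WM&GM	1	FALSE	0.05	0.95	0.15	0.97
Globus	WM&GM	1	FALSE	0.05	0.95	0.15	0.97
Vb	VB	1	FALSE	0.04	0.75	0	0.2
Not Csf	Background	1	FALSE	0	0.6	0.2	1
Not Gm	Background	1	FALSE	0.15	0.9	0.35	1
Not Vb	Background	1	FALSE	0.15	0.9	0	0.3
Not Wm	Background	1	FALSE	0.4	1	0.1	0.85
Air	Background	1	FALSE	0	0.1	0	0.1
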
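object	r	g	b	alpha1	alpha2	rho_m	sigma	r_gate	gap_threshold
O1	186	69	34	0.2	0.3	0.2	0.5	1200	3
O2	104	140	53	0.2	0.3	0.2	0.5	1200	3
O3	130	100	142	0.1	0.2	0.3	0.6	1200	3
O4	141	47	48	0.1	0.4	0.3	0.6	1200	3
O5	87	133	166	0.1	0.3	0.3	0.6	1200	3
O6	134	147	181	0.15	0.25	0.8	0.5	1200	3
O7	176	134	36	0.2	0.3	0.4	0.4	1200	3
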
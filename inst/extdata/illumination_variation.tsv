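object	saturation_morning	saturation_evening	saturation_rate	lightness_morning	lightness_evening	lightness_rate
O1	140	163	16.4	120	103	14.2
O2	102	92	9.8	121	96	20.7
O3	44	40	9.1	90	120	33.3
O4	144	128	11.1	96	88	8.3
O5	173	74	57.2	145	118	18.6
O6	32	16	50.0	114	109	4.4
O7	240	157	34.6	150	101	32.7
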
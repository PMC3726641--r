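context	partner_a	mean_a	partner_b	mean_b	total_printed
M1	solvent	12.5	protein	3.9	16.4
M2	solvent	10.7	protein	5.2	15.9
M3	solvent	12.5	protein	4.5	17.0
M4	solvent	11.3	protein	4.2	15.5
M5	solvent	11.9	protein	3.9	15.8
M6	solvent	4.8	protein	0.1	4.9
water-only	as-acceptor	11.1	as-donor	7.7	18.8
ternary-wt	solvent	14.8	protein	4.4	19.2
ternary-mut	solvent	13.3	protein	3.4	16.7
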
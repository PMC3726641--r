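block	model	replica	dH_mean	dH_sd	mTdS_mean	mTdS_sd	dG_printed	dG_sd_printed	ddG_printed
binary	M1	1	-27.6	5.2	20.2	4.3	-7.4	6.7	0.0
binary	M2	1	-27.7	4.5	19.7	4.2	-8.1	6.2	-0.7
binary	M3	1	-25.0	3.6	19.0	3.0	-5.9	4.7	1.5
binary	M4	1	-21.9	3.5	18.9	5.0	-3.1	6.1	4.3
binary	M5	1	-28.1	3.5	18.8	3.8	-9.4	5.1	-2.0
binary	M6	1	-31.1	3.7	20.1	2.5	-11.0	4.5	-3.6
ternary	wt	1	-9.4	2.5	15.8	2.5	6.5	3.5	0.0
ternary	wt	2	-11.6	3.6	17.9	2.0	6.3	4.1	-0.2
ternary	mut	1	-14.0	3.9	18.1	3.9	4.1	5.6	-2.4
ternary	mut	2	-9.1	4.4	16.2	3.6	7.0	5.7	0.5
interprotein	wt	1	-129.7	8.4	55.5	5.9	-74.2	10.3	0.0
interprotein	wt	2	-130.1	8.1	56.2	5.5	-73.9	9.8	0.3
interprotein	mut	1	-139.3	10.1	55.8	6.3	-83.5	11.9	-9.3
interprotein	mut	2	-137.0	11.7	53.5	5.6	-83.4	13.1	-9.2
interprotein	wt-egcg	1	-121.0	10.7	55.1	5.1	-65.8	11.9	8.4
interprotein	wt-egcg	2	-123.1	9.9	52.8	5.8	-70.3	11.4	3.9
interprotein	mut-egcg	1	-126.4	12.5	56.7	5.7	-69.7	13.7	4.5
interprotein	mut-egcg	2	-121.6	6.9	52.6	5.6	-70.0	8.9	4.2
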
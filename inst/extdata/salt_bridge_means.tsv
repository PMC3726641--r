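model	replica	hbond_mean	saltbridge_mean	pct_printed
wt	1	11.2	8.8	78
wt	2	10.5	7.8	74
mut	1	15.9	11.5	72
mut	2	15.6	11.3	72
wt-egcg	1	10.6	8.0	75
wt-egcg	2	10.6	8.5	80
mut-egcg	1	12.5	8.6	69
mut-egcg	2	12.5	9.5	76
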
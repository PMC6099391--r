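fraction_pct	main_signal	s_mean	s_sd	n_mean	n_sd	significant
10	C	11.54	1.46	10.82	0.98	no
15	C	14.82	1.16	10.64	1.13	yes
20	C	21.08	2.23	10.66	1.07	yes
30	C	29.14	1.65	8.92	1.18	yes
40	C	39.60	1.87	9.02	1.19	yes
50	C	47.72	1.37	8.84	1.16	yes
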
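# published chromosome-wise SSR counts and densities (per Mb) for black pepper
seq_id	ssrs	per_mb	spacing_kb
Pn1	17501	361.20	2.77
Pn2	15758	365.57	2.74
Pn3	14219	361.01	2.77
Pn4	13842	371.75	2.69
Pn5	14724	395.26	2.53
Pn6	9856	268.1	3.73
Pn7	13388	398.4	2.51
Pn8	12865	393.7	2.54
Pn9	12044	337.84	2.69
Pn10	10598	338.98	2.95
Pn11	10266	344.83	2.90
Pn12	10417	352.11	2.84
Pn13	11191	380.23	2.63
Pn14	10105	348.43	2.87
Pn15	10558	367.65	2.72
Pn16	9814	350.88	2.85
Pn17	8873	344.83	2.9
Pn18	9335	364.96	2.74
Pn19	8529	343.64	2.91
Pn20	9003	370.37	2.7
Pn21	8089	363.64	2.75
Pn22	7671	346.02	2.89
Pn23	7401	362.32	2.76
Pn24	7180	361.01	2.77
Pn25	7102	389.11	2.57
Pn26	5850	392.16	2.55
PnU	280	358.42	2.79
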
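id	n_cycles	P0	rho	alpha1	alpha2
6	11	46.0	1.01e-3	0.32	0.1
10	15	45.4	7.06e-4	0.27	0.21
25	4	31.7	1.84e-3	0.76	0.75
57	9	46.8	8.74e-4	0.23	0.21
105	20	145.0	2.05e-3	0.1	0.14
108	5	13.9	1.73e-3	0.92	0.18
151	11	34.6	7.41e-4	0.52	0.05
159	11	64.7	5.33e-4	0.57	0.6
170	17	6.4	2.28e-3	0.01	0.28
203	9	29.8	3.31e-4	1.99	0.1
213	18	23.9	6.08e-4	0.3	0.3
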
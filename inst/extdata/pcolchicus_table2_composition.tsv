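partition	pct_t	pct_c	pct_a	pct_g	pct_at	pct_gc	at_skew	gc_skew
Mitogenome	25.26	30.85	30.61	13.28	55.47	44.53	0.0958	-0.3981
PCGs	27.07	31.53	28.40	13.00	55.47	44.53	0.0240	-0.4161
PCG-1st	23.01	30.25	31.23	15.51	54.24	45.76	0.1515	-0.3221
PCG-2nd	31.42	31.01	23.84	13.73	55.26	44.74	-0.1372	-0.3862
PCG-3rd	26.77	33.32	30.15	9.76	56.92	43.08	0.0594	-0.5469
tRNA	28.03	20.74	30.75	20.48	58.78	41.22	0.0463	-0.0063
rRNA	20.90	27.24	33.81	18.05	54.71	45.29	0.2360	-0.2029
12S rRNA	19.67	28.47	32.92	18.94	52.59	47.41	0.2519	-0.2010
16S rRNA	21.64	26.51	34.34	17.51	55.98	44.02	0.2269	-0.2045
CR	32.49	25.87	27.44	14.20	59.93	40.07	-0.0843	-0.2913
CR-Domain I	29.97	27.44	30.28	12.30	60.25	39.75	0.0052	-0.3810
CR-Domain II	31.62	31.41	16.67	20.30	48.29	51.71	-0.3097	-0.2149
CR-Domain III	35.81	17.36	38.84	7.99	74.66	25.34	0.0406	-0.3696
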
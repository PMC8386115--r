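trait	chromosome	window_mb	first_bp	last_bp	n_snps	pct_genetic_variance	ppa
thw_g	22	4	4000760	4676714	1035	0.54	0.95
th_pct	2	62	62001908	62998786	310	0.62	0.69
th_pct	22	4	4000760	4676714	1035	0.57	0.97
drw_g	1	56	56000162	56998456	358	0.71	0.80
drw_g	1	166	166000511	166999195	390	3.20	0.92
drw_g	2	40	40007952	40999399	305	0.56	0.72
drw_g	3	30	30000897	30993376	386	1.15	0.83
drw_g	4	24	24000906	24996950	321	0.61	0.78
drw_g	6	8	8002588	8996459	508	1.51	0.90
drw_g	28	0	24369	999295	883	0.80	0.99
dr_pct	1	166	166000511	166999195	390	2.79	0.93
dr_pct	2	9	9012190	9990590	310	0.62	0.74
dr_pct	3	30	30000897	30993376	386	1.39	0.85
dr_pct	4	24	24000906	24996950	321	0.55	0.76
dr_pct	6	8	8002588	8996459	508	0.99	0.90
dr_pct	14	3	3001973	3999889	549	0.53	0.89
dr_pct	20	7	7000004	7998579	475	0.54	0.86
dr_pct	28	0	24369	999295	883	0.70	0.97
abfw_g	5	38	38000437	38996916	396	0.92	0.84
abfw_g	10	7	7000336	7998549	592	0.58	0.93
abfw_g	13	3	3002617	3998616	460	1.45	0.88
abfw_g	20	5	5000651	5999452	492	0.94	0.88
abfw_g	26	1	1002598	1999851	662	1.06	0.95
abf_pct	5	38	38000437	38996916	396	0.64	0.82
abf_pct	10	7	7000336	7998549	592	0.61	0.90
abf_pct	13	3	3002617	3998616	460	1.49	0.89
abf_pct	26	1	1002598	1999851	662	0.54	0.92
btw_g	17	7	7000143	7999150	667	0.64	0.92
btw_g	25	2	2001192	2887176	512	0.81	0.88
btw_g	26	2	2000388	2999606	904	0.66	0.95
btw_g	26	3	3000141	3998650	998	0.53	0.96
bt_pct	4	43	43001322	43998491	364	0.61	0.80
bt_pct	12	5	5000340	5999121	596	0.64	0.89
bt_pct	12	6	6000683	6997857	550	0.74	0.87
bt_pct	17	7	7000143	7999150	667	0.65	0.91
bt_pct	25	2	2001192	2887176	512	0.60	0.84
bt_pct	26	2	2000388	2999606	904	0.87	0.97
bt_pct	26	3	3000141	3998650	998	0.86	0.98
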
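marker_id	chromosome	position_bp	trait_group	gene_symbol	ensembl_gene_id	ref_allele	alt_allele	ref_freq	alt_freq	n_hom_ref	n_het	n_hom_alt	hw_p_reported	sift_score
rs739508259	1	166014604	DR	VWA8	ENSGALG00000016955	G	C	0.588	0.412	86	106	44	0.6262	0.01
rs314536739	22	4589985	TH	ANXA4	ENSGALG00000038783	C	T	0.738	0.262	126	98	13	0.4782	0.02
rs739048621	25	2264528	BT	novel	ENSGALG00000014643	G	A	0.947	0.052	212	25	0	0.7875	0.00
c.482C>T	26	1010017	ABF	MYBPH	ENSGALG00000000164	C	T	0.764	0.236	146	70	21	0.0071	0.04
c.383C>T	26	1053832	ABF	CEPT1	ENSGALG00000000142	C	T	0.941	0.059	209	28	0	0.7402	0.02
rs312325687	26	1086300	ABF	novel	ENSGALG00000000104	A	G	0.639	0.361	105	93	39	0.0124	0.01
rs314560661	26	1300802	ABF	AHCYL1	ENSGALG00000000329	T	C	0.941	0.059	209	28	0	0.7875	0.01
rs14297872	26	1312073	ABF	STRIP1	ENSGALG00000037995	C	T	0.932	0.068	205	32	0	0.6067	0.01
rs741234441	26	1510415	ABF	novel	ENSGALG00000000477	C	T	0.605	0.395	76	135	26	2.101E-6	0.01
rs733369312	26	1779214	ABF	PPP1R15B	ENSGALG00000000611	C	A	0.624	0.376	71	154	12	5.457E-13	0.00
rs731705610	26	1981145	ABF	CNTN2	ENSGALG00000000653	C	T	0.947	0.053	212	25	0	0.9367	0.02
rs738655377	26	3145562	BT	novel	ENSGALG00000028858	A	G	0.863	0.137	172	65	0	1.0E-4	0.00
rs736010549	26	3213394	BT	WDR77	ENSGALG00000040864	A	T	0.810	0.190	149	86	2	0.1768	0.01
rs737237434	26	3290417	BT	DDX20	ENSGALG00000001504	A	G	0.780	0.220	143	82	11	0.8671	0.01
rs14300225	26	3747346	BT	PTPN22	ENSGALG00000021656	C	T	0.084	0.916	1	38	198	0.7153	0.00
rs739340698	26	3764766	BT	AP4B1	ENSGALG00000035295	C	T	0.935	0.065	207	29	1	1.0	0.02
rs313532967	26	3947129	BT	BARL	ENSGALG00000002170	A	G	0.736	0.264	117	115	5	5.410E-5	0.00
rs741234600	26	3971333	BT	SYCP1	ENSGALG00000002511	A	C	0.950	0.050	209	28	0	0.5256	0.03
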
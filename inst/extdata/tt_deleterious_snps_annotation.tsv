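marker_id	gene_symbol	ensembl_gene_id	consequence	sift_score
rs739508259	VWA8	ENSGALG00000016955	missense_variant	0.01
rs314536739	ANXA4	ENSGALG00000038783	missense_variant	0.02
rs739048621	novel	ENSGALG00000014643	missense_variant	0.00
c.482C>T	MYBPH	ENSGALG00000000164	missense_variant	0.04
c.383C>T	CEPT1	ENSGALG00000000142	missense_variant	0.02
rs312325687	novel	ENSGALG00000000104	missense_variant	0.01
rs314560661	AHCYL1	ENSGALG00000000329	missense_variant	0.01
rs14297872	STRIP1	ENSGALG00000037995	missense_variant	0.01
rs741234441	novel	ENSGALG00000000477	missense_variant	0.01
rs733369312	PPP1R15B	ENSGALG00000000611	missense_variant	0.00
rs731705610	CNTN2	ENSGALG00000000653	missense_variant	0.02
rs738655377	novel	ENSGALG00000028858	missense_variant	0.00
rs736010549	WDR77	ENSGALG00000040864	missense_variant	0.01
rs737237434	DDX20	ENSGALG00000001504	missense_variant	0.01
rs14300225	PTPN22	ENSGALG00000021656	missense_variant	0.00
rs739340698	AP4B1	ENSGALG00000035295	missense_variant	0.02
rs313532967	BARL	ENSGALG00000002170	missense_variant	0.00
rs741234600	SYCP1	ENSGALG00000002511	missense_variant	0.03
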
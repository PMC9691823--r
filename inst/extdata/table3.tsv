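# unreportable novel-diagnosis fixture (11 participants, zero major key features)
research_id	sex	recruitment_category	gene	zygosity	consequence	hgvs_c	hgvs_p	popdb_af	cohort_af	sift	polyphen	clinvar	segregation	major_count	minor_count
52	unknown	Intellectual disability	ALMS1	het	missense_variant	NM_015120.4:c.7738A>T	NP_055935.4:p.Ile2580Phe	4.01e-6	9.9970000000000007e-05	deleterious	benign	absent	maternal	0	2
52	unknown	Intellectual disability	ALMS1	het	missense_variant	NM_015120.4:c.346C>T	NP_055935.4:p.His116Tyr	2.41e-5	0.00019994000000000001	deleterious	benign	absent	paternal	0	2
59	unknown	Hereditary spastic paraplegia	BBS1	het	missense_variant	NM_024649.5:c.235G>A	NP_078925.3:p.Glu79Lys	7.56e-4	0.00120728	deleterious	possibly_damaging	vus	unknown	0	0
59	unknown	Hereditary spastic paraplegia	BBS1	het	missense_variant	NM_024649.5:c.1714G>T	NP_078925.3:p.Gly572Cys	NA	1.27e-5	deleterious	probably_damaging	absent	unknown	0	0
60	unknown	Primary immunodeficiency	CEP290	het	frameshift_variant	NM_025114.4:c.6154_6161del	NP_079390.3:p.Asp2052LeufsTer17	0	1.27e-5	NA	NA	absent	unknown	0	0
60	unknown	Primary immunodeficiency	CEP290	het	frameshift_variant	NM_025114.4:c.7412_7415del	NP_079390.3:p.Glu2471ValfsTer13	0	1.91e-5	NA	NA	absent	unknown	0	0
61	unknown	Primary lymphoedema	CEP290	het	stop_gained	NM_025114.4:c.7048C>T	NP_079390.3:p.Gln2350Ter	1.9e-5	1.91e-5	NA	NA	likely_pathogenic	unknown	0	0
61	unknown	Primary lymphoedema	CEP290	het	missense_variant	NM_025114.4:c.4063C>T	NP_079390.3:p.Arg1355Cys	4.97e-5	9.53e-5	deleterious	probably_damaging	vus	unknown	0	0
64	unknown	Limb-girdle muscular dystrophy	CEP290	hom	missense_variant	NM_025114.4:c.4805C>T	NP_079390.3:p.Thr1602Met	2.26e-4	2.7958e-4	deleterious	possibly_damaging	conflicting	unknown	0	0
65	unknown	Undiagnosed monogenic disorders	CEP290	het	missense_variant	NM_025114.4:c.5909C>A	NP_079390.3:p.Thr1970Asn	0	1.27e-5	deleterious	probably_damaging	absent	unknown	0	0
65	unknown	Undiagnosed monogenic disorders	CEP290	het	stop_gained&frameshift_variant	NM_025114.4:c.7283_7286dup	NP_079390.3:p.Tyr2429Ter	2.11e-5	2.54e-5	NA	NA	absent	unknown	0	0
68	unknown	Early onset dementia	CEP290	het	missense_variant	NM_025114.4:c.31A>G	NP_079390.3:p.Met11Val	7.72e-5	6.35e-6	deleterious	benign	vus	unknown	0	0
68	unknown	Early onset dementia	CEP290	het	missense_variant	NM_025114.4:c.2447G>A	NP_079390.3:p.Arg816His	3.13e-5	6.35e-5	deleterious	probably_damaging	vus	unknown	0	0
69	unknown	Epilepsy plus other features	CEP290	het	missense_variant	NM_025114.4:c.2446C>T	NP_079390.3:p.Arg816Cys	5e-5	2.54e-5	deleterious	probably_damaging	vus	unknown	0	0
69	unknown	Epilepsy plus other features	CEP290	het	missense_variant	NM_025114.4:c.4741C>T	NP_079390.3:p.Leu1581Phe	1.32e-5	1.27e-5	deleterious	possibly_damaging	vus	unknown	0	0
71	unknown	Hereditary ataxia	DYNC2H1	het	missense_variant	NM_001377.3:c.10142C>T	NP_001368.2:p.Pro3381Leu	3.62e-5	1e-4	deleterious	probably_damaging	likely_pathogenic	unknown	0	0
71	unknown	Hereditary ataxia	DYNC2H1	het	missense_variant	NM_001377.3:c.3419G>T	NP_001368.2:p.Gly1140Val	3.938e-4	4.4987e-4	deleterious	benign	vus	unknown	0	0
72	female	Early onset dementia	OFD1	het	splice_acceptor_variant	NM_003611.3:c.936-1G>A	NA	0	6.35e-6	NA	NA	absent	unknown	0	0
73	female	Early onset dystonia	OFD1	het	frameshift_variant	NM_003611.3:c.1911del	NP_003602.1:p.Glu637AspfsTer29	0	6.35e-6	NA	NA	absent	unknown	0	0
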
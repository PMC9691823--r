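# reportable new-diagnosis fixture (18 participants, 30 variant rows); printed_confidence as published, rule_confidence from the stated confidence rule
research_id	printed_confidence	rule_confidence	sex	recruitment_category	gene	zygosity	consequence	hgvs_c	hgvs_p	popdb_af	cohort_af	sift	polyphen	clinvar	segregation	acmg_class	major_count	minor_count	systems	excluded_listed
45	confident	confident	male	Cone dysfunction syndrome	ALMS1	het	frameshift_variant	NM_015120.4:c.10775del	NP_055935.4:p.Thr3592LysfsTer6	5.23e-5	4.77e-4	NA	NA	pathogenic	paternal	pathogenic	1	0	M: Oph	TRUE
45	confident	confident	male	Cone dysfunction syndrome	ALMS1	het	structural_variant	NC_000002.12:g.(73424245_73544334inv;73424245_73427355dup;73484777_73544334dup)	NA	NA	NA	NA	NA	absent	maternal	likely_pathogenic	1	0	M: Oph	TRUE
47	possible	possible	female	Bardet-Biedl syndrome	BBS10	hom	missense_variant	NM_024685.4:c.1790G>A	NP_078961.3:p.Gly597Asp	0	2.54e-5	deleterious	probably_damaging	absent	bi_parental	vus	4	0	M: Ren, oph, skel, endo/met	TRUE
48	confident	confident	male	Rod dysfunction syndrome	NPHP1	hom	missense_variant	NM_001128178.3:c.1027G>A	NP_000263.2:p.Gly343Arg	1.155e-4	3.4312e-4	deleterious	probably_damaging	pathogenic	one_parent_other_unknown	pathogenic	1	1	M: Ren m: Oph	TRUE
49	possible	possible	female	Cystic kidney disease	CEP290	hom	intron_variant	NM_025114.4:c.6011+874G>T	NA	0	3.81e-5	NA	NA	absent	one_parent_other_unknown	vus	1	1	M: Ren m: CVS	FALSE
50	possible	possible	female	Syndromic cleft lip and/or cleft palate	OFD1	het	missense_variant	NM_003611.3:c.635G>C	NP_003602.1:p.Arg212Pro	0	1.27e-5	deleterious	possibly_damaging	absent	de_novo	vus	3	0	M: Fac/ora (n=2), skel	TRUE
51	probable	possible	male	Joubert syndrome	CEP290	het	missense_variant	NM_025114.4:c.104T>G	NP_079390.3:p.Val35Gly	0	1e-4	deleterious	probably_damaging	absent	maternal	vus	4	0	M: Oph, neu (n=3)	TRUE
51	probable	possible	male	Joubert syndrome	CEP290	het	stop_gained	NM_025114.4:c.5668G>T	NP_079390.3:p.Gly1890Ter	9.49e-5	2.5e-4	NA	NA	pathogenic	paternal	vus	4	0	M: Oph, neu (n=3)	TRUE
53	possible	possible	male	Cystic kidney disease	ALMS1	het	missense_variant	NM_015120.4:c.8735A>G	NP_055935.4:p.Gln2912Arg	0	5e-5	deleterious	possibly_damaging	absent	unknown	vus	2	2	M: Ren, endo/met m: GI, CVS	FALSE
53	possible	possible	male	Cystic kidney disease	ALMS1	het	missense_variant	NM_015120.4:c.7412A>G	NP_055935.4:p.Asp2471Gly	0	5e-5	deleterious	probably_damaging	absent	unknown	vus	2	2	M: Ren, endo/met m: GI, CVS	FALSE
54	possible	possible	female	Rod-cone dystrophy	ALMS1	het	missense_variant	NM_015120.4:c.10831A>G	NP_055935.4:p.Arg3611Gly	3.22e-5	5e-5	deleterious	possibly_damaging	absent	unknown	vus	2	1	M: Oph, ren m: Resp	FALSE
54	possible	possible	female	Rod-cone dystrophy	ALMS1	het	missense_variant	NM_015120.4:c.10377C>G	NP_055935.4:p.Ile3459Met	3.63e-5	5e-5	deleterious	possibly_damaging	vus	unknown	vus	2	1	M: Oph, ren m: Resp	FALSE
55	confident	confident	female	Single autosomal recessive mutation in rare disease	ALMS1	het	frameshift_variant	NM_015120.4:c.11794del	NP_055935.4:p.Glu3932LysfsTer18	3.99e-6	1.27e-5	NA	NA	absent	unknown	pathogenic	4	0	M: Oph, endo/met (n=2), CVS	FALSE
55	confident	confident	female	Single autosomal recessive mutation in rare disease	ALMS1	het	frameshift_variant	NM_015120.4:c.1735del	NP_055935.4:p.Arg579GlyfsTer17	1.61e-5	3.18e-5	NA	NA	pathogenic	unknown	pathogenic	4	0	M: Oph, endo/met (n=2), CVS	FALSE
56	probable	probable	male	Intellectual disability	ALMS1	het	frameshift_variant	NM_015120.4:c.10775del	NP_055935.4:p.Thr3592LysfsTer6	5.23e-5	4.7656e-4	NA	NA	pathogenic	unknown	pathogenic	1	2	M: Sens m: CVS, neu	FALSE
56	probable	probable	male	Intellectual disability	ALMS1	het	missense_variant	NM_015120.4:c.7510G>T	NP_055935.4:p.Ala2504Ser	8.93e-5	1.9062e-4	deleterious	probably_damaging	vus	unknown	vus	1	2	M: Sens m: CVS, neu	FALSE
57	possible	possible	male	Congenital hearing impairment	ALMS1	het	missense_variant	NM_015120.4:c.11429A>G	NP_055935.4:p.Tyr3810Cys	NA	1.27e-5	deleterious	probably_damaging	absent	maternal	vus	1	0	M: Sens	FALSE
57	possible	possible	male	Congenital hearing impairment	ALMS1	het	missense_variant	NM_015120.4:c.9148A>G	NP_055935.4:p.Ile3050Val	2.007e-4	1.2708e-4	deleterious	possibly_damaging	vus	paternal	vus	1	0	M: Sens	FALSE
58	possible	possible	female	Syndromic congenital heart disease	BBS1	het	missense_variant	NM_024649.5:c.734C>T	NP_078925.3:p.Pro245Leu	7.16e-5	6.35e-6	deleterious	benign	vus	unknown	vus	1	1	M: Neu m: CVS	FALSE
58	possible	possible	female	Syndromic congenital heart disease	BBS1	het	missense_variant	NM_024649.5:c.1313C>G	NP_078925.3:p.Thr438Arg	7.96e-5	4.45e-5	deleterious	probably_damaging	vus	maternal	vus	1	1	M: Neu m: CVS	FALSE
62	confident	confident	female	Epilepsy plus other features	CEP290	het	frameshift_variant	NM_025114.4:c.5434_5435del	NP_079390.3:p.Glu1812LysfsTer5	1.14e-5	4.45e-5	NA	NA	pathogenic	unknown	pathogenic	2	0	M: Oph, Neu	FALSE
62	confident	confident	female	Epilepsy plus other features	CEP290	het	intron_variant	NM_025114.4:c.2991+1655A>G	NA	0	4.0031e-4	NA	NA	pathogenic	unknown	pathogenic	2	0	M: Oph, Neu	FALSE
63	confident	confident	female	Cystic kidney disease	CEP290	het	start_lost	NM_025114.4:c.2T>A	NP_079390.3:p.Met1?	4.07e-6	2.54e-5	NA	NA	pathogenic	paternal	pathogenic	2	0	M: Ren, oph	FALSE
63	confident	confident	female	Cystic kidney disease	CEP290	het	stop_gained	NM_025114.4:c.4966G>T	NP_079390.3:p.Glu1656Ter	3.6e-5	1.59e-4	NA	NA	pathogenic	maternal	pathogenic	2	0	M: Ren, oph	FALSE
66	possible	possible	male	Leber congenital amaurosis or early onset severe retinal dystrophy	CEP290	hom	missense_variant	NM_025114.4:c.182T>C	NP_079390.3:p.Met61Thr	NA	2.54e-5	deleterious	possibly_damaging	absent	bi_parental	vus	3	0	M: Oph, neu (n=2)	FALSE
67	possible	possible	female	Ultra-rare undescribed monogenic disorders	CEP290	hom	missense_variant	NM_025114.4:c.5284C>T	NP_079390.3:p.Arg1762Cys	3.78e-5	9.53e-5	deleterious	possibly_damaging	vus	unknown	vus	2	1	M: Oph, neu m: GI	FALSE
70	confident	confident	female	Proteinuric renal disease	DYNC2H1	het	synonymous_variant	NM_001377.3:c.11049G>A	NP_001368.2:p.Pro3683=	1.21e-5	1.4996e-4	NA	NA	likely_pathogenic	paternal	likely_pathogenic	2	0	M: Ren, skel	FALSE
70	confident	confident	female	Proteinuric renal disease	DYNC2H1	het	structural_variant	NC_000011.9:g.103445518_10350188del	NA	NA	NA	NA	NA	absent	maternal	likely_pathogenic	2	0	M: Ren, skel	FALSE
75	possible	probable	male	Distal myopathies	TMEM67	het	missense_variant	NM_153704.6:c.2035G>C	NP_714915.3:p.Glu679Gln	0	5e-5	deleterious	probably_damaging	absent	unknown	vus	1	0	M: Ren	FALSE
75	possible	probable	male	Distal myopathies	TMEM67	het	missense_variant	NM_153704.6:c.755T>C	NP_714915.3:p.Met252Thr	8.36e-5	2e-4	deleterious	benign	pathogenic	unknown	pathogenic	1	0	M: Ren	FALSE
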
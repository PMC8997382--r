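sample_id	gene	hgvs_p	effect	af	popfreq_max	cosmic_id	oncokb_class	sift_call	polyphen_call	grantham_score	clinvar_class
N01	KIT	p.V560del	inframe_indel	0.42	0	COSM1255	oncogenic				
N02	KIT	p.W557_K558del	inframe_indel	0.38	0	COSM1252	oncogenic				
N03	KIT	p.V559D	missense	0.35	0	COSM1257	oncogenic	deleterious	probably_damaging	81	
N04	KIT	p.L576P	missense	0.31	0	COSM1290	oncogenic	deleterious	probably_damaging	98	
N05	KIT	p.K550_K558del	inframe_indel	0.44	0	COSM1251	oncogenic				
N06	KIT	p.D820Y	missense	0.27	0	COSM1263	oncogenic	deleterious	probably_damaging	160	
N07	KIT	p.V654A	missense	0.22	0	COSM12706	oncogenic	deleterious	probably_damaging	64	
N08	KIT	p.N822K	missense	0.29	0	COSM1322	oncogenic	deleterious	probably_damaging	94	
N09	KIT	p.E554_V559del	inframe_indel	0.36	0	COSM1253	oncogenic				
N10	KIT	p.?	splice_site	0.33	0						uncertain_significance
N11	PDGFRA	p.D842Y	missense	0.4	0	COSM736	oncogenic	deleterious	probably_damaging	160	
N12	NF1	p.Q1815*	nonsense	0.3	0						
N13	NF1	p.Q1815*	nonsense	0.28	0						
N14	NF1	p.F1247fs	frameshift	0.26	0						
N09	RB1	p.E492K	missense	0.24	0			deleterious	possibly_damaging	56	
N11	RB1	p.R320G	missense	0.21	0			deleterious	probably_damaging	125	
N06	BRCA2	p.G2508S	missense	0.18	0			tolerated	possibly_damaging	56	uncertain_significance
N01	SDHC	p.T32N	missense	0.19	0			tolerated	possibly_damaging	65	uncertain_significance
N04	ATM	p.I2185T	missense	0.23	0			tolerated	possibly_damaging	89	uncertain_significance
N02	RECQL4	c.1621-4G>C	other	0.25	0						likely_benign
N15	RECQL4	c.1621-4G>C	other	0.22	0						likely_benign
N05	BRCA1	p.G1350C	missense	0.17	0			tolerated	possibly_damaging	159	uncertain_significance
N08	RAD52	p.V374I	missense	0.2	0			tolerated	benign	29	uncertain_significance
N10	PALB2	p.R825T	missense	0.16	0			tolerated	possibly_damaging	71	uncertain_significance
N13	FANCA	p.R1409W	missense	0.19	0			tolerated	possibly_damaging	101	uncertain_significance
N14	FANCD2	p.A439V	missense	0.18	0			tolerated	benign	64	uncertain_significance
N16	FANCG	p.S603F	missense	0.21	0			tolerated	possibly_damaging	155	uncertain_significance
N03	ERCC3	p.K11E	missense	0.22	0			tolerated	benign	56	uncertain_significance
N07	ERCC3	p.K11E	missense	0.2	0			tolerated	benign	56	uncertain_significance
N12	ERCC3	p.S764L	missense	0.24	0	COSM3042186		deleterious	probably_damaging	145	
N15	ERCC5	p.R71H	missense	0.19	0			tolerated	benign	29	uncertain_significance
N06	PRKDC	p.M3846I	missense	0.17	0			tolerated	benign	10	uncertain_significance
N10	PRKDC	p.P2456A	missense	0.18	0			tolerated	benign	27	uncertain_significance
N16	PRKDC	p.G1030V	missense	0.16	0			tolerated	possibly_damaging	109	uncertain_significance
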
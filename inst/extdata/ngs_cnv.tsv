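sample_id	gene	copy_number
N01	CHEK2	1
N02	CHEK2	1
N03	CHEK2	1
N04	CHEK2	1
N05	CHEK2	1
N06	CHEK2	1
N07	RB1	1
N08	RB1	1
N09	RB1	1
N10	RB1	1
N07	BRCA2	1
N08	BRCA2	1
N01	BLM	1
N02	BLM	1
N07	BLM	1
N12	BLM	1
N13	BLM	1
N01	ATM	1
N03	ATM	1
N08	ATM	1
N14	ATM	1
N02	CHEK1	1
N04	CHEK1	1
N15	CHEK1	1
N05	ATR	1
N03	RAD51	1
N07	RAD51	1
N16	RAD51	1
N03	RAD51B	1
N07	MRE11	1
N16	MRE11	1
N12	SDHC	7
N13	SDHC	4
N14	SDHC	4
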
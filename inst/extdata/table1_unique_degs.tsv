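number	accession	gene_symbol	description	rpkm	stage
1	comp30822_c1_seq1	BMP-3B	bone morphogenetic protein 3/3B	0.415	NP
2	comp26554_c0_seq1	GPR64	G protein-coupled receptor 64	0.386	NP
3	comp1343_c1_seq1	MYSM1	protein MYSM1	0.958	D
4	comp14291_c0_seq1	MYB	myb proto-oncogene protein	1.720	D
5	comp15472_c0_seq1	GZMH	granzyme H (cathepsin G-like 2)	5.420	D
6	comp17324_c0_seq1	GJB2	gap junction protein, beta 2	2.511	D
7	comp25676_c0_seq1	ITGA11	integrin alpha 11	0.659	D
8	comp28858_c0_seq1	ZSCAN20	KRAB domain-containing zinc finger protein	0.821	D
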
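variant_id	chrom	pos	effect_allele	other_allele	effect_weight	gene_label	pathway
rs7909719	.	0	C	A	0.19913257635247669	C3	complement
rs7956519	.	0	G	T	-0.14791154946014676	ADAMTS9-AS2	ecm
rs1579383	.	0	C	A	-0.10323144476426623	ADAM19	ecm
rs2571948	.	0	C	T	0.16185705077753973	CFH	complement
rs8504365	.	0	A	G	-0.11013661387347116	ABCA1	lipid
rs0794408	.	0	T	G	-0.3887423495259924	LOC0002	
rs6736925	.	0	G	A	0.26099999999999995	DECOY03	
rs6705995	.	0	C	T	0.37311836549780014	LOC0001	
rs4568680	.	0	A	G	-0.42185802921184912	ARMS2/HTRA1	arms2_htra1
rs4578425	.	0	T	G	0.18110713518071223	CFB/C2	complement
rs5771031	.	0	T	G	-0.27201424604364033	DECOY01	
rs8738072	.	0	T	C	-0.10331147162908245	COL4A3	ecm
rs9560086	.	0	A	G	-0.11551442826700231	APOE	lipid
rs7200852	.	0	T	G	0.31358413239924088	DECOY02	
rs4547543	.	0	A	G	-0.2397509506029594	ARMS2/HTRA1	arms2_htra1
rs9201916	.	0	T	G	2.9209911637588895	DECOY04	
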
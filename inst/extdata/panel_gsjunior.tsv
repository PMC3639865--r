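Locus	Exon	Reference	FwdRegion	FwdPos	RevRegion	RevPos	Length	Pool	PoolingFactor
A	2	A*01:01:01:01	exon1	51-67	intron2	66-83	576	long	1
A	3	A*01:01:01:01	intron2	120-141	intron3	65-83	521	long	1
A	4	A*01:01:01:01	intron3	110-130	intron4	76-91	541	long	1
B	1	B*07:02:01	5NCR	210-230	intron1	45-59	278	short	0.5
B	2	B*07:02:01	intron1	45-59	intron2	25-43	467	long	1
B	3	B*07:02:01	intron2	100-114	intron3	36-52	462	long	1
B	4	B*07:02:01	intron3	110-128	exon5	27-45	558	long	1
C	1	C*01:02:01	5NCR	210-230	intron1	42-62	279	short	0.5
C	2	C*01:02:01	intron1	42-62	intron2	42-58	487	long	1
C	3	C*01:02:01	intron2	120-140	intron3	65-83	531	long	1
C	4	C*01:02:01	intron3	90-107	intron4	76-94	584	long	1
C	7	C*01:02:01	intron6	62-80	exon8	14-33	366	short	0.5
DRB	2	DRB1*01:01:01	intron1	120-141	exon2	250-270	545	long	6
DRB	3	DRB1*01:01:01	intron2	90-110	intron3	1-20	459	long	1
DQB1	2	DQB1*02:01:01	intron1|exon2	141-150|1-9	exon2|intron2	268-270|1-16	356	short	0.5
DQB1	3	DQB1*02:01:01	exon3	43-62	intron3	1-27	357	short	0.5
DPB1	2	DPB1*03:01:01	intron1	120-147	intron2	3-27	408	long	1
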
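# aggregated gene-pair feature set for glioma expression clusters (27 pairs, 5 clusters)
cluster	gene_a	gene_b
cluster1	POSTN	C1QL1
cluster1	CD46	PDGFRA
cluster1	ACSL3	TF
cluster1	DCX	LGR4
cluster1	EGFR	PMP2
cluster1	TMSB15A	LXN
cluster1	TCEAL2	MYO5C
cluster2	HILPDA	BANF1
cluster2	NDRG1	APLP2
cluster2	IFITM3	BNIP3
cluster2	MRFAP1L1	ZNF395
cluster3	PDPN	DLL3
cluster3	TMEM100	DYNLT3
cluster3	EMP3	FERMT1
cluster3	RBP1	BMP2
cluster3	EPHB1	IGFBP2
cluster3	NNMT	SH3GL2
cluster4	P4HA1	LMO3
cluster4	CDKN2A	MYC
cluster4	MAOB	VEGFA
cluster4	C21orf62	SEMA5A
cluster4	APLNR	PHLDA1
cluster5	GULP1	CA10
cluster5	SLC7A11	NKX2-2
cluster5	MYO5C	UGT8
cluster5	C1QL1	LTBP1
cluster5	ECM2	GPR17
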
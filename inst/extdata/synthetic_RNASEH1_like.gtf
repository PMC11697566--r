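synthetic_RNASEH1_like_chr001	uorfkit	exon	1	1407	.	+	.	gene_id "synthetic_RNASEH1_like_tx001"; transcript_id "synthetic_RNASEH1_like_tx001";
synthetic_RNASEH1_like_chr001	uorfkit	CDS	101	907	.	+	0	gene_id "synthetic_RNASEH1_like_tx001"; transcript_id "synthetic_RNASEH1_like_tx001";
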
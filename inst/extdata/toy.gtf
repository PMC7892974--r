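chr1	toy	exon	101	200	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	toy	exon	301	500	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	toy	CDS	151	200	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr1	toy	CDS	301	400	.	+	.	gene_id "g1"; transcript_id "g1.t1";
chr2	toy	exon	101	400	.	-	.	gene_id "g2"; transcript_id "g2.t1";
chr2	toy	CDS	151	350	.	-	.	gene_id "g2"; transcript_id "g2.t1";
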
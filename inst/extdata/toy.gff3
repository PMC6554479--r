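##gff-version 3
chr1	test	gene	101	200	.	+	.	ID=gene1
chr1	test	mRNA	101	200	.	+	.	ID=mRNA1;Parent=gene1
chr1	test	gene	151	250	.	-	.	ID=gene2
chr2	test	gene	11	60	.	+	.	ID=gene3
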
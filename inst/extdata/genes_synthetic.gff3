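##gff-version 3
##sequence-region 19 1 60000000
19	synthetic	gene	27365475	27369000	.	+	.	ID=gene1;Name=GENEA
19	synthetic	gene	27500000	27550000	.	-	.	ID=gene2;Name=GENEB
19	synthetic	gene	31250000	31260000	.	+	.	ID=gene3;Name=GENEC
5	synthetic	gene	26900000	26949409	.	+	.	ID=gene4;Name=GENED
5	synthetic	gene	40000000	40010000	.	.	.	ID=gene5;Name=GENEE
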
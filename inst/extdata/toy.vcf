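##fileformat=VCFv4.2
##contig=<ID=1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##expected_dosage=rows are subjects S1,S2,S3; columns rs1,rs2; matrix = [[1,2],[0,NA],[2,1]]; rs3 is multi-allelic and must be skipped
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	100	rs1	A	G	.	PASS	.	GT	0|1	0/0	1/1
1	200	rs2	C	T	.	PASS	.	GT	1/1	./.	1/0
1	300	rs3	G	A,T	.	PASS	.	GT	0/1	1/2	0/0
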
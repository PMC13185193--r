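##fileformat=VCFv4.2
##contig=<ID=1,length=1000000>
##contig=<ID=2,length=800000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
1	100	rs1	A	C	.	PASS	.	GT	0/0	0/1	1/1
1	5000	rs2	G	T	.	PASS	.	GT	0/1	./.	0/0
2	200	rs3	T	A	.	PASS	.	GT	1|1	0|1	0/0
2	9000	rs4	C	G	.	PASS	.	GT	0/0	0/0	./.
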
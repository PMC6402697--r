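##fileformat=VCFv4.2
##contig=<ID=chr1,length=300>
##contig=<ID=chr2,length=200>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
chr1	22	.	G	C	.	PASS	.	GT	0/0	0/0	0/1
chr1	23	.	A	C	.	PASS	.	GT	0/0	0/1	0/0
chr1	60	.	A	C	.	PASS	.	GT	0/0	0/0	0/1
chr1	91	.	A	C	.	PASS	.	GT	0/1	0/0	0/0
chr1	135	.	C	T	.	PASS	.	GT	0/0	0/0	0/1
chr1	151	.	C	G	.	PASS	.	GT	0/1	0/0	0/0
chr1	188	.	G	A	.	PASS	.	GT	0/0	0/1	0/0
chr1	269	.	T	C	.	PASS	.	GT	0/0	0/1	0/0
chr1	288	.	A	T	.	PASS	.	GT	0/1	0/0	0/0
chr2	101	.	T	A	.	PASS	.	GT	0/0	0/0	0/1
chr2	133	.	A	C	.	PASS	.	GT	0/1	0/0	0/0
chr2	172	.	C	A	.	PASS	.	GT	0/0	0/1	0/0
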
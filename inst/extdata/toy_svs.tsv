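chrom1	pos1	chrom2	pos2	type	homology	sample
chr1	1000	chr1	60000	deletion	3	S1
chr1	5000	chr1	2e+06	tandem_duplication	0	S1
chr1	200	chr1	1500	inversion	7	S2
chr2	100	chr2	9e+06	foldback_inversion	1	S2
chr1	50	chr2	77	translocation	0	S3
chr1	10	chr1	2e+07	deletion	12	S3
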
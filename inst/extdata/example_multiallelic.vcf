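##fileformat=VCFv4.2
##source=synthetic_example
##contig=<ID=1>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
1	1000	rs1	A	G,T	.	PASS	.	GT	0/1	1/2
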
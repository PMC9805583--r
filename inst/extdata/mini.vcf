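##fileformat=VCFv4.2
##contig=<ID=chr20>
##INFO=<ID=AF,Number=1,Type=Float,Description="Estimated Alternate Allele Frequency">
##INFO=<ID=MAF,Number=1,Type=Float,Description="Estimated Minor Allele Frequency">
##INFO=<ID=R2,Number=1,Type=Float,Description="Estimated Imputation Accuracy (R-square)">
##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description="Imputed site">
##INFO=<ID=TYPED,Number=0,Type=Flag,Description="Genotyped site">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated Alternate Allele Dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
chr20	60291	chr20:60291:G:T	G	T	.	PASS	AF=0.25;MAF=0.25;R2=0.91;IMPUTED	GT:DS	0|1:0.950	0|0:0.050	1|0:1.020
chr20	60341	chr20:60341:A:G	A	G	.	PASS	AF=0.5;MAF=0.5;R2=0.99;TYPED	GT:DS	1|1:2.000	0|1:0.980	0|0:0.010
chr20	60510	chr20:60510:C:A	C	A	.	PASS	AF=0.1;MAF=0.1;R2=0.42;IMPUTED	GT:DS	0|0:0.100	0|0:0.000	0|1:0.900
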
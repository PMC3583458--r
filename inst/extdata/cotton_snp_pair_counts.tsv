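# Allele-pair composition of the published cotton (A/D subgenome)
# homoeo-SNP index: counts of single-allele records by ordered
# (A-genome allele, D-genome allele) pair, plus the number of records
# with multiple allele possibilities in one genome (type=multi).
type	allele_A	allele_D	count
pair	A	T	190935
pair	A	C	132443
pair	A	G	409059
pair	T	A	190468
pair	T	C	407605
pair	T	G	132678
pair	C	A	117349
pair	C	T	363240
pair	C	G	86903
pair	G	A	363609
pair	G	T	117194
pair	G	C	87509
multi	NA	NA	34697
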
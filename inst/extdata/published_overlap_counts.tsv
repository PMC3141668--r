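quantity	value
rhesus_validated_total	3038166
converted_to_hg19	2775850
shared_with_human_dbsnp132	90086
human_dbsnp132_snps	29100846
human_genome_chr1_22_X_bp	3036287275
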
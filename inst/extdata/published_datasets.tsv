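name	animal	type
17573_sanger	17573	reseq
17573_solid	17573	reseq
r1766	r1766	reseq
r02120	r02120	reseq
subspecies	pooled_subspecies	published
mamusnp	pooled_mamusnp	published
encode	pooled_encode	published
dbsnp	unknown	published
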
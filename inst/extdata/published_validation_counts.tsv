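source	target	method	count
17573_solid	17573_sanger	positional	1056266
r1766	17573_sanger	positional	22665
r1766	17573_solid	positional	412920
r02120	17573_sanger	positional	5734
r02120	17573_solid	positional	103323
r02120	r1766	positional	328910
subspecies	17573_sanger	positional	4185
subspecies	17573_solid	positional	6519
subspecies	r1766	positional	1070
subspecies	r02120	positional	226
mamusnp	17573_sanger	positional	389
mamusnp	17573_solid	positional	781
mamusnp	r1766	positional	159
mamusnp	r02120	positional	33
mamusnp	subspecies	positional	19
encode	17573_sanger	positional	29
encode	17573_solid	positional	76
encode	r1766	positional	14
encode	r02120	positional	7
encode	subspecies	positional	0
encode	mamusnp	positional	1
dbsnp	17573_sanger	positional	11
dbsnp	17573_solid	positional	12
dbsnp	r1766	positional	5
dbsnp	r02120	positional	0
dbsnp	subspecies	positional	0
dbsnp	mamusnp	positional	0
dbsnp	encode	positional	0
17573_sanger	17573_solid	egeno	421234
17573_sanger	r1766	egeno	64584
17573_sanger	r02120	egeno	41607
17573_sanger	subspecies	egeno	34339
17573_solid	r1766	egeno	109485
17573_solid	r02120	egeno	61941
17573_solid	subspecies	egeno	9
r1766	17573_solid	egeno	155454
r1766	r02120	egeno	93016
r1766	subspecies	egeno	17
r02120	17573_solid	egeno	41836
r02120	r1766	egeno	69424
r02120	subspecies	egeno	3
subspecies	17573_solid	egeno	677
subspecies	r1766	egeno	743
subspecies	r02120	egeno	443
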
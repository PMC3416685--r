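platform	n_regions	total_bases	inside_snps	near_snps	far_snps
SureSelect	165637	37800000	65231	44854	39195
TrueSeq	201071	62100000	95818	117866	104305
1000G	8496	1400000	1548	3011	4128
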
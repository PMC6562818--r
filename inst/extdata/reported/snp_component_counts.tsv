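label	count
homozygous	28862
heterozygous	6292
non_synonymous	1045
synonymous	2190
gene	18332
mRNA	22327
total	35154
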
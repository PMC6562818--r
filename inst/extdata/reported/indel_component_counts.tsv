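label	count
insertion	11211
deletion	12098
CDS	1051
UTR	796
mRNA	11949
total	23309
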
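chrom	start	end	phenotype
11	4412041	5661311	IgY_level
11	13531246	14463528	SRBC_antibody_response
16	1	535270	IgY_level
19	8974480	9730805	SRBC_antibody_response
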
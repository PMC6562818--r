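position	alleles	variant_type	consistent
Chr16:213135	C/G	SNP	yes
Chr16:213142	A/G	SNP	yes
Chr16:213221	T/G	SNP	yes
Chr16:213160	T/G	SNP	no
Chr16:61196	C/G	SNP	yes
Chr16:61211	A/C	SNP	yes
Chr11:4464202	G/A	SNP	yes
Chr11:4478491	C/A	SNP	yes
Chr11:4478592	T/C	SNP	yes
Chr11:4478634	T/C	SNP	yes
Chr11:4480688	G/T	SNP	yes
Chr11:4480721	C/A	SNP	yes
Chr11:4479104	C/T	SNP	yes
Chr11:4479176	G/A	SNP	yes
Chr11:4479218	A/G	SNP	yes
Chr11:4479254	C/T	SNP	yes
Chr11:4480840	C/T	SNP	yes
Chr11:4480934	T/A	SNP	yes
Chr11:4480961	G/A	SNP	yes
Chr11:4480971	G/A	SNP	yes
Chr11:4481057	G/A	SNP	yes
Chr11:4481115	A/G	SNP	yes
Chr11:4478592	T/C	SNP	no
Chr11:4478634	T/C	SNP	no
Chr16:74016-74024	CCACTGCCA	deletion	yes
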
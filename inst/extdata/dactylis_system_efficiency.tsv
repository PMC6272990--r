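item	SSR	IT-ISJ
n_primers	21	15
total_loci	196	99
mean_loci_per_primer	9.33	6.6
PPB	100	100
Ibav	0.49	0.54
EMR	9.33	6.60
MI	4.58	3.54
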
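statistic	value
It	0.448
Is	0.321
Is_over_It	0.717
S_prime	0.283
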
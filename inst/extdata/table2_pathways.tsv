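pathway	total	expected	hits	p	fdr	empirical_p
Neurotrophin signaling pathway	123	1.34	10	5.60e-07	1.21e-04	0.1
Cardiac muscle contraction	12	0.131	4	5.81e-06	6.30e-04	<0.01
Cell cycle	124	1.35	8	4.74e-05	3.43e-03	0.14
Hypertrophic cardiomyopathy	25	0.272	4	1.34e-04	7.25e-03	<0.01
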
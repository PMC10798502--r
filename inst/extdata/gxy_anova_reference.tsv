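source	df	SS	MS	pct_total_SS
Rep	1	3.4	3.4	0.01
Genotype	52	11675.69	224.53	40.80
Year	2	7458.75	3729.38	26.07
Genotype x Year	104	9171.76	88.19	32.05
Residuals	156	293.47	1.88	NA
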
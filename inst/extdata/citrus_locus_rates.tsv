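locus	p_distance	mu_per_year	mu_per_generation
HYB	0.0336	3.31e-9	6.62e-8
LGT	0.05	4.24e-9	8.47e-8
MDH	0.0227	1.93e-9	3.85e-8
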
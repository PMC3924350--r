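module	r	p	de_genes	size
red	0.63	1.08E-04	74	307
brown	0.55	1.23E-03	88	846
pink	0.47	6.28E-03	30	150
blue	0.35	4.77E-02	104	936
black	0.13	0.47	1	306
grey	0.04	0.85	15	3339
magenta	-0.08	0.65	0	130
green	-0.40	2.44E-02	10	445
turquoise	-0.63	1.08E-04	224	1125
yellow	-0.74	1.35E-06	196	719
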
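taxon	direction	or	ci_low	ci_high	pval
g.Comamonas B	risk	1.23	1.05	1.44	0.008
f.Halomonadaceae	risk	1.43	1.11	1.84	0.004
g.Lachnospirales	risk	1.22	1.06	1.40	0.003
f.UBA6960	risk	1.22	1.05	1.43	0.008
g.Pseudomonadales	protective	0.65	0.49	0.86	0.002
o.Blautia hansenii	protective	0.89	0.82	0.96	0.003
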
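exposure	mediator	outcome	beta_all	beta_indir
g.Comamonas B	ADP to glycine ratio	IVDD	0.2093615	0.01629125
f.Halomonadaceae	1,3-dimethylurate levels	IVDD	0.3602667	0.03257683
f.Halomonadaceae	3-hydroxy-2-methylpyridine sulfate levels	IVDD	0.3602667	0.04525938
f.UBA6960	Histidine levels	IVDD	0.205047	0.02412032
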
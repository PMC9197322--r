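# published genome-wide SSR class counts for the 26-chromosome black pepper assembly
class	count	n_motifs
mono	137676	4
di	62083	12
tri	29560	60
tetra	7297	136
penta	562	104
hexa	920	141
compound	38132	34569
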
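genotype,d_strain,d_seedling
JaCg144,0,0.894
JaCg151,0.228,0.539
JaCg32,0.351,0.411
JaCg205,0.935,0.189
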
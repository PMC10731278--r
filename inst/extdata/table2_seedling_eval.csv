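genotype,F1,F2,F3,U1,U2,U3,D,rank
JaCg144,2.759,0.892,2.313,1.000,0.666,1.000,0.894,1
JaCg151,2.318,-0.756,-2.577,0.920,0.381,0.000,0.539,2
JaCg32,-2.722,2.821,-0.560,0.000,1.000,0.412,0.411,3
JaCg205,-2.355,-2.957,0.824,0.067,0.000,0.695,0.189,4
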
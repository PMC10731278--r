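strain,D,rank
JaCg205,0.935,1
ChCg77,0.871,2
ChCg57,0.487,3
JaCg32,0.351,4
JaCg151,0.228,5
JaCg49,0.004,6
JaCg41,0,7
JaCg45,0,8
JaCg57,0,9
JaCg144,0,10
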
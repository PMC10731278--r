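component,weight
F1,0.455
F2,0.317
F3,0.228
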
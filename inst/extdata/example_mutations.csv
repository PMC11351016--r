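complex,mutation,ddg
SYN,AA2G,0.50
SYN,AA5L,-1.20
SYN,AB3W,2.05
SYN,AB7S,0.15
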
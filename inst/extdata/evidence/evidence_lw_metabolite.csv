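metabolite,vip,p_bh,p_censored,r2
glucose,1.90,0.151,FALSE,0.04
glucuronic acid,1.03,0.006,FALSE,0.17
lactate,4.21,0.008,FALSE,0.15
alanine,1.30,0.024,FALSE,0.11
glutamine,1.10,0.075,FALSE,0.07
glycine,1.21,0.007,FALSE,0.15
leucine,1.12,0.002,FALSE,0.22
proline,2.50,0.001,TRUE,0.32
serine,1.08,0.033,FALSE,0.10
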
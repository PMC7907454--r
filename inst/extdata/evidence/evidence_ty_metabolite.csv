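metabolite,vip,p_bh,p_censored,r2
glucose,1.00,0.547,FALSE,0.01
lactate,4.03,0.046,FALSE,0.10
alanine,1.26,0.080,FALSE,0.08
glutamine,1.65,0.043,FALSE,0.11
glycine,1.39,0.010,FALSE,0.15
leucine,1.38,0.001,TRUE,0.25
proline,2.68,0.001,TRUE,0.28
serine,1.33,0.043,FALSE,0.11
valine,1.13,0.010,FALSE,0.16
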
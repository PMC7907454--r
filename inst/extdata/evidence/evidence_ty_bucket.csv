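metabolite,n_important_peaks,n_peaks,n_important_buckets,p_bh,p_censored
lactate,2,2,14,0.001,FALSE
mannose,8,9,21,0.230,FALSE
sorbitol,5,5,18,0.240,FALSE
xylitol,3,3,8,0.690,FALSE
alanine,2,2,9,0.004,FALSE
arginine,4,4,9,0.040,FALSE
glutamine,3,3,19,0.001,TRUE
isoleucine,6,6,23,0.003,FALSE
leucine,3,3,10,0.690,FALSE
lysine,8,12,15,0.070,FALSE
methionine,3,3,12,0.230,FALSE
pyroglutamic acid,4,4,18,0.001,FALSE
ethanolamine,2,2,4,0.410,FALSE
glycerol,3,3,11,0.002,FALSE
isovaleric acid,3,3,10,0.001,FALSE
methylmalonic acid,2,2,5,0.005,FALSE
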
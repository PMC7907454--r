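metabolite,n_important_peaks,n_peaks,n_important_buckets,p_bh,p_censored
lactate,2,2,12,0.001,FALSE
mannose,8,9,21,0.030,FALSE
sorbitol,5,5,19,0.040,FALSE
xylitol,3,3,9,0.230,FALSE
alanine,2,2,6,0.001,TRUE
arginine,4,4,10,0.002,FALSE
glutamic acid,8,8,15,0.001,TRUE
glutamine,3,3,16,0.001,TRUE
isoleucine,6,6,23,0.001,TRUE
lysine,6,12,13,0.002,FALSE
methionine,3,3,17,0.030,FALSE
pyroglutamic acid,4,4,19,0.001,TRUE
glycerol,3,3,12,0.001,TRUE
methylmalonic acid,2,2,6,0.001,TRUE
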
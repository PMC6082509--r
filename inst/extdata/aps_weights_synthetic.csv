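predictor,op,threshold,points
age,ge,65,1
age,ge,80,2
ckd,true,,2
heart_failure,true,,1
diabetes,true,,1
liver_disease,true,,2
resp_rate_ge20,true,,1
avpu_below_alert,true,,3
news,ge,5,2
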
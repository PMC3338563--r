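crop_id,dr_lower,dr_median,dr_upper,is_staple
apple,0.4,0.65,1.0,FALSE
soybean,0.1,0.25,0.5,FALSE
almond,0.4,0.65,1.0,FALSE
wheat,0,0,0,TRUE
maize,0,0,0,TRUE
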
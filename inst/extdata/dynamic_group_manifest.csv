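subject_id,week,injected_activity_mbq,body_weight_g,glucose_pre_mmol_l,glucose_post_mmol_l,route
dyn-group-mean,1,9.0,25.9,9.9,9.9,iv
dyn-group-mean,2,9.6,26.9,10.0,10.0,iv
dyn-group-mean,3,10.3,27.0,10.0,10.0,iv
dyn-group-mean,4,11.0,26.9,10.7,10.7,iv
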
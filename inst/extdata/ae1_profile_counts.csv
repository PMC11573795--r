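age_group,compartment,p,n_0
infant,on_capillary,1841,1374
infant,above_pillar,1241,442
adult,on_capillary,1306,859
adult,above_pillar,347,311
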
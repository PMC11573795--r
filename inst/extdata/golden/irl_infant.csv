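compartment,n_0,p,n_e,irl,chi2
on_capillary,1374,1841,1084.77,1.27,77.12
above_pillar,442,1241,731.23,0.6,114.4
total,1816,3082,1816,1.87,191.52
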
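compartment,n_0,p,n_e,irl,chi2
on_capillary,859,1306,924.39,0.93,4.63
above_pillar,311,347,245.61,1.27,17.41
total,1170,1653,1170,2.2,22.04
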
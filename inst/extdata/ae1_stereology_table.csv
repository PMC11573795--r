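subject,age_group,v_par,vv_sept_par,v_sept,vv_ae1_sept,v_ae1,vv_comp1,v_comp1,vv_comp2,v_comp2,vv_nuc,v_nuc,vv_mito,v_mito,q_comp1,q_comp2
C1,infant,115,0.325,37.3,0.154,5.7,0.613,3.5,0.273,1.6,0.114,0.6,0.060,0.347,76.7,23.3
C2,infant,157,0.288,45.3,0.117,5.3,0.494,2.6,0.391,2.1,0.115,0.6,0.069,0.364,74.9,25.1
C3,infant,372,0.143,53.1,0.105,5.6,0.557,3.1,0.367,2.1,0.076,0.4,0.060,0.337,75.6,24.4
A2,adult,3285,0.085,279.0,0.083,23.0,0.691,15.9,0.217,5.0,0.092,2.1,0.073,1.690,71.7,28.3
A4,adult,3510,0.198,695.0,0.107,74.3,0.748,55.6,0.174,12.9,0.078,5.8,0.055,4.055,76.3,23.7
A8,adult,5355,0.114,612.3,0.107,65.6,0.749,49.1,0.181,11.9,0.070,4.6,0.062,4.056,71.5,28.5
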
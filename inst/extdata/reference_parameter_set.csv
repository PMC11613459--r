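set_id,k_D,k_dD,k_dE,k_de,k_ADP_ATP,D_D,D_E,D_d,D_de
2827,1.66,0.22,0.82,0.33,1.09,16,10,0.2,0.2
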
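region,n_samples,rho_b,IR_f,Q0_Cr,Q0_Ni,Q0_Cu,Q0_Zn,Q0_As,Q0_Cd,Q0_Pb
north,48,1.35,33.92,51.60,25.75,20.50,67.30,8.65,0.091,17.65
northwest,55,1.18,80.30,65.70,32.55,22.45,69.25,12.33,0.115,20.43
northeast,14,1.41,115.89,52.65,22.10,18.55,75.55,7.65,0.093,26.50
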
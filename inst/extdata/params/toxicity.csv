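metal,SF,RfD_f,RfD_s,RfD_b
Cr,4.20e1,3.00e-3,2.9e-5,6.00e-5
Ni,8.40e-1,2.00e-2,2.00e-2,5.40e-3
Cu,,4.00e-2,4.00e-2,1.20e-2
Zn,,3.00e-1,3.00e-1,6.00e-2
As,1.51e1,3.00e-4,3.00e-4,1.20e-3
Cd,6.30,1.00e-3,1.00e-3,1.00e-5
Pb,,3.50e-3,3.50e-3,5.20e-4
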
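element,Z,atomic_weight,mean_ionization_eV,k_binding_keV,kalpha_keV
H,1,1.008,19.2,0.0136,NA
C,6,12.011,78,0.2842,0.277
N,7,14.007,82,0.4099,0.3924
O,8,15.999,95,0.5431,0.5249
P,15,30.974,173,2.1455,2.0137
Ca,20,40.078,191,4.0381,3.6917
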
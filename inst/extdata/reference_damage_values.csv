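w_um,dt_s,quantity,value,units,note
100,320,Z,120,percent,reported relative damaged volume for pike cleithrum bone irradiated at 18 keV through a 100 um pinhole
20,320,Z,150,percent,reported relative damaged volume for the 20 um pinhole series
10,320,Z,240,percent,reported relative damaged volume for the 10 um pinhole series
5,320,Z,260,percent,reported relative damaged volume for the 5 um pinhole series
100,320,k,0.33,percent_per_s,first-order damage accumulation rate for the 100 um series
20,320,k,0.07,percent_per_s,first-order damage accumulation rate for the 20 um series
10,320,k,0.02,percent_per_s,first-order damage accumulation rate for the 10 um series
5,320,k,0.02,percent_per_s,first-order damage accumulation rate for the 5 um series
1,320,zeta_fold,10,fold,predicted damage-to-beam diameter ratio for a 1 um beam
0.1,320,zeta_fold,75,fold,predicted damage-to-beam diameter ratio for a 0.1 um beam
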
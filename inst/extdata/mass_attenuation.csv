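element,energy_keV,mu_rho_cm2_g
H,2,1.059
H,3,0.5612
H,4,0.4546
H,5,0.4193
H,6,0.4042
H,8,0.3914
H,10,0.3854
H,15,0.3764
H,20,0.3695
H,30,0.357
H,40,0.3458
H,50,0.3355
H,60,0.326
H,80,0.3091
H,100,0.2944
C,2,302.6
C,3,90.33
C,4,37.78
C,5,19.12
C,6,10.95
C,8,4.576
C,10,2.373
C,15,0.8071
C,20,0.442
C,30,0.2562
C,40,0.2076
C,50,0.1871
C,60,0.1753
C,80,0.161
C,100,0.1514
N,2,476.9
N,3,145.6
N,4,61.66
N,5,31.44
N,6,18.09
N,8,7.562
N,10,3.879
N,15,1.236
N,20,0.6178
N,30,0.3066
N,40,0.2288
N,50,0.198
N,60,0.1817
N,80,0.1639
N,100,0.1529
O,2,694.9
O,3,217.1
O,4,93.15
O,5,47.9
O,6,27.7
O,8,11.63
O,10,5.952
O,15,1.836
O,20,0.8651
O,30,0.3779
O,40,0.2585
O,50,0.2132
O,60,0.1907
O,80,0.1678
O,100,0.1551
P,2,305.6
P,2.1454,254
P,2.1456,3050
P,3,1211
P,4,560
P,5,303
P,6,182
P,8,80.0
P,10,41.0
P,15,12.8
P,20,5.45
P,30,1.70
P,40,0.81
P,50,0.492
P,60,0.349
P,80,0.232
P,100,0.187
Ca,2,800
Ca,3,275
Ca,4.0380,130
Ca,4.0382,1130
Ca,5,630
Ca,6,380
Ca,8,172
Ca,10,93.4
Ca,15,27.9
Ca,20,11.9
Ca,30,3.67
Ca,40,1.66
Ca,50,0.94
Ca,60,0.61
Ca,80,0.353
Ca,100,0.257
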
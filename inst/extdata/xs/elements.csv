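symbol,Z,A,k_edge,l3_edge
H,1,1.008,0.0136,NA
C,6,12.011,0.2838,NA
N,7,14.007,0.4099,NA
O,8,15.999,0.5431,NA
Na,11,22.99,1.0721,NA
Si,14,28.085,1.8389,0.0996
Cl,17,35.453,2.8224,0.2022
Ar,18,39.948,3.206,0.2484
Ca,20,40.078,4.0381,0.3462
Fe,26,55.845,7.112,0.7081
Sn,50,118.71,29.2001,3.9288
Ba,56,137.327,37.4406,5.247
La,57,138.905,38.9246,5.4827
W,74,183.84,69.525,10.2068
Pb,82,207.2,88.0045,13.0352
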
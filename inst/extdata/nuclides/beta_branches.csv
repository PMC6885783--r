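nuclide,e_max_keV,e_mean_keV,yield
Cs137,511.5,174.3,0.9460
Cs137,1175.6,416.3,0.0540
Co60,317.9,95.8,0.9988
I131,247.9,69.4,0.0208
I131,333.8,96.6,0.0723
I131,606.3,191.6,0.8960
La140,1245.0,430.0,0.0560
La140,1348.0,470.0,0.4410
La140,1678.0,610.0,0.2030
La140,2164.0,820.0,0.0560
Na24,1392.9,554.5,0.9990
Eu152,695.7,224.5,0.1390
Eu152,1474.5,535.1,0.0810
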
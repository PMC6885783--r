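nuclide,energy_keV,yield
Am241,26.34,0.0240
Am241,59.54,0.3590
Ba133,30.97,0.6210
Ba133,35.00,0.1440
Ba133,53.16,0.0214
Ba133,79.61,0.0265
Ba133,80.997,0.3290
Ba133,276.40,0.0716
Ba133,302.85,0.1834
Ba133,356.01,0.6205
Ba133,383.85,0.0894
Eu152,121.78,0.2853
Eu152,244.70,0.0755
Eu152,344.28,0.2659
Eu152,411.12,0.0223
Eu152,443.96,0.0280
Eu152,778.90,0.1293
Eu152,867.38,0.0423
Eu152,964.06,0.1451
Eu152,1085.87,0.1011
Eu152,1089.74,0.0173
Eu152,1112.07,0.1367
Eu152,1212.95,0.0142
Eu152,1299.14,0.0163
Eu152,1408.01,0.2087
Cs137,32.06,0.0570
Cs137,36.40,0.0132
Cs137,661.66,0.8510
Co60,1173.23,0.9985
Co60,1332.49,0.9998
Tc99m,140.51,0.8900
I131,80.19,0.0262
I131,284.31,0.0612
I131,364.49,0.8150
I131,636.99,0.0716
I131,722.91,0.0177
La140,328.76,0.2030
La140,432.49,0.0290
La140,487.02,0.4550
La140,751.64,0.0433
La140,815.77,0.2328
La140,867.85,0.0550
La140,919.55,0.0266
La140,925.19,0.0690
La140,1596.21,0.9540
La140,2521.40,0.0346
Na24,1368.63,0.9999
Na24,2754.01,0.9986
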
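# element=O Z=8 A=15.9990 k_edge_keV=0.5431 l3_edge_keV=NA
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,5.990712e+00,1.928605e-01,2.871426e-01,0.000000e+00
10.861763,4.592220e+00,1.922513e-01,2.567676e-01,0.000000e+00
11.797789,3.517977e+00,1.915953e-01,2.283847e-01,0.000000e+00
12.814478,2.693399e+00,1.908894e-01,2.021891e-01,0.000000e+00
13.918782,2.060901e+00,1.901305e-01,1.782706e-01,0.000000e+00
15.118251,1.576065e+00,1.893152e-01,1.566282e-01,0.000000e+00
16.421085,1.204658e+00,1.884400e-01,1.371902e-01,0.000000e+00
17.836193,9.203181e-01,1.875015e-01,1.198367e-01,0.000000e+00
19.373249,7.027643e-01,1.864961e-01,1.044187e-01,0.000000e+00
21.042763,5.364034e-01,1.854202e-01,9.077472e-02,0.000000e+00
22.856150,4.092577e-01,1.842702e-01,7.874148e-02,0.000000e+00
24.825808,3.121327e-01,1.830424e-01,6.816101e-02,0.000000e+00
26.340000,2.570269e-01,1.821134e-01,6.139268e-02,0.000000e+00
26.965203,2.379758e-01,1.817335e-01,5.888437e-02,0.000000e+00
29.288964,1.813810e-01,1.803400e-01,5.077321e-02,0.000000e+00
30.970000,1.509727e-01,1.793497e-01,4.589154e-02,0.000000e+00
31.812977,1.382075e-01,1.788586e-01,4.370018e-02,0.000000e+00
34.554501,1.052852e-01,1.772862e-01,3.754864e-02,0.000000e+00
37.532278,8.018918e-02,1.756203e-01,3.221222e-02,0.000000e+00
40.766670,6.106510e-02,1.738582e-01,2.759424e-02,0.000000e+00
44.279789,4.649614e-02,1.719980e-01,2.360724e-02,0.000000e+00
48.095656,3.540019e-02,1.700381e-01,2.017244e-02,0.000000e+00
52.240360,2.695120e-02,1.679776e-01,1.721926e-02,0.000000e+00
53.160000,2.544351e-02,1.675296e-01,1.665132e-02,0.000000e+00
56.742239,2.051891e-02,1.658158e-01,1.468475e-02,0.000000e+00
59.540000,1.750709e-02,1.645107e-01,1.337953e-02,0.000000e+00
61.632073,1.562266e-02,1.635532e-01,1.251313e-02,0.000000e+00
66.943295,1.189604e-02,1.611905e-01,1.065518e-02,0.000000e+00
72.712218,9.059808e-03,1.587295e-01,9.067668e-03,0.000000e+00
78.978285,6.901272e-03,1.561726e-01,7.712820e-03,0.000000e+00
80.190000,6.564049e-03,1.556915e-01,7.485958e-03,0.000000e+00
80.997000,6.351340e-03,1.553733e-01,7.340359e-03,0.000000e+00
85.784339,5.258455e-03,1.535232e-01,6.557746e-03,0.000000e+00
93.176913,4.008046e-03,1.507852e-01,5.573917e-03,0.000000e+00
101.206551,3.056193e-03,1.479637e-01,4.736665e-03,0.000000e+00
109.928154,2.331482e-03,1.450641e-01,4.024727e-03,0.000000e+00
119.401351,1.779580e-03,1.420928e-01,3.419818e-03,0.000000e+00
121.780000,1.668636e-03,1.413740e-01,3.289509e-03,0.000000e+00
129.690913,1.359158e-03,1.390569e-01,2.906255e-03,0.000000e+00
140.510000,1.047381e-03,1.360596e-01,2.482948e-03,0.000000e+00
140.867192,1.038781e-03,1.359638e-01,2.470611e-03,0.000000e+00
153.006600,7.945395e-04,1.328214e-01,2.101416e-03,0.000000e+00
160.610000,6.791910e-04,1.309582e-01,1.911752e-03,0.000000e+00
166.192137,6.082508e-04,1.296380e-01,1.788887e-03,0.000000e+00
180.513955,4.660855e-04,1.264220e-01,1.524698e-03,0.000000e+00
196.069973,3.575247e-04,1.231819e-01,1.301768e-03,0.000000e+00
212.966551,2.745668e-04,1.199259e-01,1.114090e-03,0.000000e+00
223.200000,2.364777e-04,1.180734e-01,1.021248e-03,0.000000e+00
231.319213,2.111239e-04,1.166622e-01,9.565680e-04,0.000000e+00
244.700000,1.767044e-04,1.144417e-01,8.644103e-04,0.000000e+00
251.253438,1.625630e-04,1.133987e-01,8.248821e-04,0.000000e+00
272.905521,1.253578e-04,1.101426e-01,7.153659e-04,0.000000e+00
276.400000,1.204589e-04,1.096426e-01,7.002726e-04,0.000000e+00
284.300000,1.102946e-04,1.085363e-01,6.683946e-04,0.000000e+00
296.423499,9.682280e-05,1.069008e-01,6.248969e-04,0.000000e+00
302.850000,9.057172e-05,1.060628e-01,6.041972e-04,0.000000e+00
321.968169,7.491249e-05,1.036795e-01,5.507983e-04,0.000000e+00
344.280000,6.092970e-05,1.010874e-01,5.011467e-04,0.000000e+00
349.714183,5.806796e-05,1.004843e-01,4.907519e-04,0.000000e+00
356.010000,5.497577e-05,9.979857e-02,4.794332e-04,0.000000e+00
364.490000,5.115401e-05,9.889613e-02,4.653233e-04,0.000000e+00
379.851245,4.510051e-05,9.732019e-02,4.427225e-04,0.000000e+00
383.850000,4.368595e-05,9.692179e-02,4.374017e-04,0.000000e+00
411.100000,3.548754e-05,9.432717e-02,4.063568e-04,0.000000e+00
412.585406,3.510325e-05,9.419145e-02,4.048964e-04,0.000000e+00
443.900000,2.817387e-05,9.145508e-02,3.786157e-04,0.000000e+00
448.140475,2.738380e-05,9.110183e-02,3.756379e-04,0.000000e+00
486.759547,2.141317e-05,8.805450e-02,3.534622e-04,0.000000e+00
487.020000,2.137929e-05,8.803492e-02,3.533388e-04,0.000000e+00
511.000000,1.855216e-05,8.628374e-02,3.431844e-04,0.000000e+00
528.706666,1.678690e-05,8.505211e-02,3.370270e-04,0.000000e+00
574.268631,1.319543e-05,8.209687e-02,3.251352e-04,0.000000e+00
623.756956,1.040164e-05,7.919063e-02,3.167444e-04,0.000000e+00
636.990000,9.796356e-06,7.846056e-02,3.150618e-04,0.000000e+00
661.660000,8.793284e-06,7.714748e-02,3.124035e-04,0.000000e+00
677.510000,8.223674e-06,7.633493e-02,3.109738e-04,0.000000e+00
722.900000,6.854276e-06,7.413097e-02,3.078094e-04,0.000000e+00
735.895281,6.521930e-06,7.353108e-02,3.071060e-04,0.000000e+00
778.900000,5.571945e-06,7.163529e-02,3.052533e-04,0.000000e+00
799.311987,5.189089e-06,7.078018e-02,3.045781e-04,0.000000e+00
815.770000,4.907207e-06,7.011019e-02,3.041091e-04,0.000000e+00
867.380000,4.153066e-06,6.811354e-02,3.029799e-04,0.000000e+00
868.193708,4.142548e-06,6.808325e-02,3.029655e-04,0.000000e+00
943.011398,3.318637e-06,6.544121e-02,3.019603e-04,0.000000e+00
964.060000,3.129710e-06,6.474505e-02,3.017653e-04,0.000000e+00
1024.276598,2.668205e-06,6.285492e-02,3.013471e-04,1.567209e-06
1085.870000,2.292258e-06,6.106198e-02,3.010689e-04,4.392901e-05
1112.070000,2.155611e-06,6.033814e-02,3.009818e-04,6.194846e-05
1112.544928,2.153246e-06,6.032522e-02,3.009804e-04,6.227510e-05
1173.230000,1.879897e-06,5.873015e-02,3.008290e-04,1.040122e-04
1208.419894,1.744323e-06,5.785294e-02,3.007650e-04,1.282146e-04
1212.950000,1.727931e-06,5.774240e-02,3.007578e-04,1.313302e-04
1299.140000,1.455199e-06,5.573575e-02,3.006526e-04,1.906087e-04
1312.557006,1.418595e-06,5.543889e-02,3.006406e-04,1.998365e-04
1332.490000,1.366710e-06,5.500508e-02,3.006245e-04,2.135457e-04
1368.630000,1.279641e-06,5.423968e-02,3.005998e-04,2.384015e-04
1408.010000,1.193943e-06,5.343515e-02,3.005781e-04,2.654857e-04
1425.668265,1.158304e-06,5.308389e-02,3.005698e-04,2.776305e-04
1548.527030,9.496174e-07,5.078872e-02,3.005300e-04,3.621284e-04
1596.210000,8.837771e-07,4.996181e-02,3.005203e-04,3.949231e-04
1681.973304,7.817356e-07,4.855413e-02,3.005079e-04,4.539082e-04
1826.919480,6.462099e-07,4.638082e-02,3.004958e-04,5.535971e-04
1984.356575,5.364151e-07,4.426942e-02,3.004891e-04,6.618769e-04
2155.361011,4.471436e-07,4.222049e-02,3.004856e-04,7.794878e-04
2341.101971,3.742915e-07,4.023447e-02,3.004836e-04,9.072339e-04
2521.400000,3.202055e-07,3.850583e-02,3.004827e-04,1.031237e-03
2542.849393,3.146170e-07,3.831171e-02,3.004826e-04,1.045989e-03
2754.010000,2.671125e-07,3.651636e-02,3.004821e-04,1.191218e-03
2761.982653,2.655518e-07,3.645241e-02,3.004821e-04,1.196701e-03
3000.000000,2.250565e-07,3.465664e-02,3.004818e-04,1.360401e-03
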
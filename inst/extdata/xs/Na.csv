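# element=Na Z=11 A=22.9900 k_edge_keV=1.0721 l3_edge_keV=NA
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,1.743813e+01,1.845439e-01,4.322982e-01,0.000000e+00
10.861763,1.345663e+01,1.839610e-01,3.895767e-01,0.000000e+00
11.797789,1.037604e+01,1.833333e-01,3.489347e-01,0.000000e+00
12.814478,7.994602e+00,1.826579e-01,3.108139e-01,0.000000e+00
13.918782,6.155234e+00,1.819317e-01,2.755126e-01,0.000000e+00
15.118251,4.735730e+00,1.811515e-01,2.431870e-01,0.000000e+00
16.421085,3.641136e+00,1.803141e-01,2.138671e-01,0.000000e+00
17.836193,2.797737e+00,1.794161e-01,1.874822e-01,0.000000e+00
19.373249,2.148377e+00,1.784540e-01,1.638895e-01,0.000000e+00
21.042763,1.648774e+00,1.774245e-01,1.429015e-01,0.000000e+00
22.856150,1.264657e+00,1.763241e-01,1.243088e-01,0.000000e+00
24.825808,9.695266e-01,1.751493e-01,1.078960e-01,0.000000e+00
26.340000,8.012522e-01,1.742603e-01,9.736311e-02,0.000000e+00
26.965203,7.429112e-01,1.738968e-01,9.345261e-02,0.000000e+00
29.288964,5.690096e-01,1.725633e-01,8.077897e-02,0.000000e+00
30.970000,4.751452e-01,1.716157e-01,7.312900e-02,0.000000e+00
31.812977,4.356358e-01,1.711458e-01,6.968902e-02,0.000000e+00
34.554501,3.333998e-01,1.696413e-01,6.001110e-02,0.000000e+00
37.532278,2.550715e-01,1.680472e-01,5.158780e-02,0.000000e+00
40.766670,1.950883e-01,1.663611e-01,4.427538e-02,0.000000e+00
44.279789,1.491733e-01,1.645811e-01,3.794311e-02,0.000000e+00
48.095656,1.140411e-01,1.627058e-01,3.247253e-02,0.000000e+00
52.240360,8.716897e-02,1.607340e-01,2.775681e-02,0.000000e+00
53.160000,8.236047e-02,1.603054e-01,2.684855e-02,0.000000e+00
56.742239,6.662136e-02,1.586655e-01,2.370007e-02,0.000000e+00
59.540000,5.696719e-02,1.574166e-01,2.160731e-02,0.000000e+00
61.632073,5.091411e-02,1.565004e-01,2.021675e-02,0.000000e+00
66.943295,3.890977e-02,1.542396e-01,1.723082e-02,0.000000e+00
72.712218,2.973714e-02,1.518848e-01,1.467515e-02,0.000000e+00
78.978285,2.272924e-02,1.494381e-01,1.249070e-02,0.000000e+00
80.190000,2.163188e-02,1.489777e-01,1.212462e-02,0.000000e+00
80.997000,2.093931e-02,1.486733e-01,1.188962e-02,0.000000e+00
85.784339,1.737570e-02,1.469030e-01,1.062581e-02,0.000000e+00
93.176913,1.328615e-02,1.442831e-01,9.035440e-03,0.000000e+00
101.206551,1.016212e-02,1.415832e-01,7.680500e-03,0.000000e+00
109.928154,7.775506e-03,1.388086e-01,6.527155e-03,0.000000e+00
119.401351,5.952021e-03,1.359655e-01,5.546213e-03,0.000000e+00
121.780000,5.584709e-03,1.352777e-01,5.334765e-03,0.000000e+00
129.690913,4.558536e-03,1.330605e-01,4.712557e-03,0.000000e+00
140.510000,3.522027e-03,1.301924e-01,4.024686e-03,0.000000e+00
140.867192,3.493390e-03,1.301008e-01,4.004627e-03,0.000000e+00
153.006600,2.678964e-03,1.270939e-01,3.403958e-03,0.000000e+00
160.610000,2.293439e-03,1.253110e-01,3.095039e-03,0.000000e+00
166.192137,2.056003e-03,1.240478e-01,2.894763e-03,0.000000e+00
180.513955,1.579279e-03,1.209705e-01,2.463575e-03,0.000000e+00
196.069973,1.214270e-03,1.178700e-01,2.098922e-03,0.000000e+00
212.966551,9.346253e-04,1.147544e-01,1.791049e-03,0.000000e+00
223.200000,8.059740e-04,1.129818e-01,1.638311e-03,0.000000e+00
231.319213,7.202328e-04,1.116315e-01,1.531672e-03,0.000000e+00
244.700000,6.036808e-04,1.095067e-01,1.379306e-03,0.000000e+00
251.253438,5.557381e-04,1.085087e-01,1.313764e-03,0.000000e+00
272.905521,4.294179e-04,1.053931e-01,1.131371e-03,0.000000e+00
276.400000,4.127628e-04,1.049146e-01,1.106118e-03,0.000000e+00
284.300000,3.781872e-04,1.038560e-01,1.052667e-03,0.000000e+00
296.423499,3.323192e-04,1.022911e-01,9.794382e-04,0.000000e+00
302.850000,3.110182e-04,1.014892e-01,9.444497e-04,0.000000e+00
321.968169,2.576029e-04,9.920866e-02,8.536683e-04,0.000000e+00
344.280000,2.098299e-04,9.672833e-02,7.683791e-04,0.000000e+00
349.714183,2.000425e-04,9.615124e-02,7.503851e-04,0.000000e+00
356.010000,1.894627e-04,9.549505e-02,7.307266e-04,0.000000e+00
364.490000,1.763801e-04,9.463153e-02,7.061157e-04,0.000000e+00
379.851245,1.556424e-04,9.312355e-02,6.664152e-04,0.000000e+00
383.850000,1.507935e-04,9.274232e-02,6.570117e-04,0.000000e+00
411.100000,1.226659e-04,9.025959e-02,6.016156e-04,0.000000e+00
412.585406,1.213464e-04,9.012972e-02,5.989841e-04,0.000000e+00
443.900000,9.753317e-05,8.751135e-02,5.511227e-04,0.000000e+00
448.140475,9.481552e-05,8.717334e-02,5.456299e-04,0.000000e+00
486.759547,7.425868e-05,8.425741e-02,5.041382e-04,0.000000e+00
487.020000,7.414192e-05,8.423868e-02,5.039039e-04,0.000000e+00
511.000000,6.439453e-05,8.256301e-02,4.844655e-04,0.000000e+00
528.706666,5.830316e-05,8.138449e-02,4.725014e-04,0.000000e+00
574.268631,4.589617e-05,7.855669e-02,4.489001e-04,0.000000e+00
623.756956,3.622951e-05,7.577577e-02,4.317041e-04,0.000000e+00
636.990000,3.413312e-05,7.507718e-02,4.281811e-04,0.000000e+00
661.660000,3.065715e-05,7.382073e-02,4.225495e-04,0.000000e+00
677.510000,2.868216e-05,7.304322e-02,4.194827e-04,0.000000e+00
722.900000,2.393048e-05,7.093429e-02,4.125772e-04,0.000000e+00
735.895281,2.277643e-05,7.036027e-02,4.110160e-04,0.000000e+00
778.900000,1.947561e-05,6.854623e-02,4.068450e-04,0.000000e+00
799.311987,1.814441e-05,6.772800e-02,4.052996e-04,0.000000e+00
815.770000,1.716393e-05,6.708690e-02,4.042169e-04,0.000000e+00
867.380000,1.453907e-05,6.517635e-02,4.015711e-04,0.000000e+00
868.193708,1.450245e-05,6.514737e-02,4.015369e-04,0.000000e+00
943.011398,1.163150e-05,6.261925e-02,3.991204e-04,0.000000e+00
964.060000,1.097264e-05,6.195312e-02,3.986425e-04,0.000000e+00
1024.276598,9.362213e-06,6.014449e-02,3.976043e-04,2.061988e-06
1085.870000,8.049209e-06,5.842886e-02,3.969006e-04,5.779772e-05
1112.070000,7.571681e-06,5.773623e-02,3.966776e-04,8.150604e-05
1112.544928,7.563414e-06,5.772387e-02,3.966739e-04,8.193580e-05
1173.230000,6.607660e-06,5.619759e-02,3.962821e-04,1.368496e-04
1208.419894,6.133361e-06,5.535820e-02,3.961145e-04,1.686928e-04
1212.950000,6.076003e-06,5.525243e-02,3.960954e-04,1.727921e-04
1299.140000,5.121202e-06,5.333231e-02,3.958163e-04,2.507853e-04
1312.557006,4.992986e-06,5.304826e-02,3.957843e-04,2.629263e-04
1332.490000,4.811220e-06,5.263315e-02,3.957410e-04,2.809636e-04
1368.630000,4.506108e-06,5.190076e-02,3.956742e-04,3.136666e-04
1408.010000,4.205700e-06,5.113092e-02,3.956152e-04,3.493015e-04
1425.668265,4.080736e-06,5.079481e-02,3.955927e-04,3.652804e-04
1548.527030,3.348595e-06,4.859861e-02,3.954832e-04,4.764550e-04
1596.210000,3.117445e-06,4.780736e-02,3.954563e-04,5.196032e-04
1681.973304,2.759031e-06,4.646038e-02,3.954214e-04,5.972102e-04
1826.919480,2.282645e-06,4.438078e-02,3.953870e-04,7.283717e-04
1984.356575,1.896355e-06,4.236043e-02,3.953680e-04,8.708362e-04
2155.361011,1.581998e-06,4.039985e-02,3.953577e-04,1.025578e-03
2341.101971,1.325244e-06,3.849948e-02,3.953521e-04,1.193654e-03
2521.400000,1.134482e-06,3.684538e-02,3.953493e-04,1.356806e-03
2542.849393,1.114763e-06,3.665963e-02,3.953491e-04,1.376215e-03
2754.010000,9.470795e-07,3.494170e-02,3.953475e-04,1.567294e-03
2761.982653,9.415685e-07,3.488051e-02,3.953474e-04,1.574508e-03
3000.000000,7.985177e-07,3.316218e-02,3.953466e-04,1.789890e-03
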
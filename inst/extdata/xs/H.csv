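# element=H Z=1 A=1.0080 k_edge_keV=0.0136 l3_edge_keV=NA
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,9.851107e-04,3.826358e-01,2.454272e-02,0.000000e+00
10.861763,7.416202e-04,3.814271e-01,2.131762e-02,0.000000e+00
11.797789,5.582711e-04,3.801256e-01,1.847667e-02,0.000000e+00
12.814478,4.202251e-04,3.787252e-01,1.598149e-02,0.000000e+00
13.918782,3.162993e-04,3.772195e-01,1.379612e-02,0.000000e+00
15.118251,2.380677e-04,3.756019e-01,1.188731e-02,0.000000e+00
16.421085,1.791826e-04,3.738655e-01,1.022450e-02,0.000000e+00
17.836193,1.348624e-04,3.720035e-01,8.779763e-03,0.000000e+00
19.373249,1.015064e-04,3.700088e-01,7.527666e-03,0.000000e+00
21.042763,7.640308e-05,3.678742e-01,6.445126e-03,0.000000e+00
22.856150,5.751107e-05,3.655926e-01,5.511295e-03,0.000000e+00
24.825808,4.329360e-05,3.631568e-01,4.707433e-03,0.000000e+00
26.340000,3.532798e-05,3.613136e-01,4.202173e-03,0.000000e+00
26.965203,3.259392e-05,3.605598e-01,4.016783e-03,0.000000e+00
29.288964,2.454142e-05,3.577950e-01,3.424434e-03,0.000000e+00
30.970000,2.026435e-05,3.558302e-01,3.073393e-03,0.000000e+00
31.812977,1.848089e-05,3.548559e-01,2.917195e-03,0.000000e+00
34.554501,1.391928e-05,3.517364e-01,2.483447e-03,0.000000e+00
37.532278,1.048558e-05,3.484311e-01,2.113008e-03,0.000000e+00
40.766670,7.900645e-06,3.449352e-01,1.796992e-03,0.000000e+00
44.279789,5.954417e-06,3.412446e-01,1.527673e-03,0.000000e+00
48.095656,4.488861e-06,3.373562e-01,1.298360e-03,0.000000e+00
52.240360,3.385072e-06,3.332680e-01,1.103273e-03,0.000000e+00
53.160000,3.189418e-06,3.323793e-01,1.065982e-03,0.000000e+00
56.742239,2.553581e-06,3.289791e-01,9.374353e-04,0.000000e+00
59.540000,2.167451e-06,3.263896e-01,8.526302e-04,0.000000e+00
61.632073,1.927072e-06,3.244900e-01,7.965713e-04,0.000000e+00
66.943295,1.454891e-06,3.198024e-01,6.770165e-04,0.000000e+00
72.712218,1.098919e-06,3.149198e-01,5.756364e-04,0.000000e+00
78.978285,8.304687e-07,3.098470e-01,4.897551e-04,0.000000e+00
80.190000,7.887580e-07,3.088923e-01,4.754399e-04,0.000000e+00
80.997000,7.624836e-07,3.082612e-01,4.662632e-04,0.000000e+00
85.784339,6.279498e-07,3.045904e-01,4.170919e-04,0.000000e+00
93.176913,4.751089e-07,2.991583e-01,3.557065e-04,0.000000e+00
101.206551,3.597096e-07,2.935603e-01,3.039504e-04,0.000000e+00
109.928154,2.725382e-07,2.878076e-01,2.604250e-04,0.000000e+00
119.401351,2.066553e-07,2.819126e-01,2.239448e-04,0.000000e+00
121.780000,1.934739e-07,2.804864e-01,2.161665e-04,0.000000e+00
129.690913,1.568334e-07,2.758893e-01,1.935040e-04,0.000000e+00
140.510000,1.201422e-07,2.699426e-01,1.689544e-04,0.000000e+00
140.867192,1.191337e-07,2.697526e-01,1.682485e-04,0.000000e+00
153.006600,9.058721e-08,2.635181e-01,1.474492e-04,0.000000e+00
160.610000,7.717677e-08,2.598214e-01,1.370652e-04,0.000000e+00
166.192137,6.895576e-08,2.572022e-01,1.304788e-04,0.000000e+00
180.513955,5.255114e-08,2.508217e-01,1.167916e-04,0.000000e+00
196.069973,4.009964e-08,2.443932e-01,1.059056e-04,0.000000e+00
212.966551,3.063982e-08,2.379333e-01,9.738899e-05,0.000000e+00
223.200000,2.631592e-08,2.342579e-01,9.345776e-05,0.000000e+00
231.319213,2.344565e-08,2.314582e-01,9.085108e-05,0.000000e+00
244.700000,1.956053e-08,2.270526e-01,8.735189e-05,0.000000e+00
251.253438,1.796857e-08,2.249834e-01,8.593733e-05,0.000000e+00
272.905521,1.379391e-08,2.185233e-01,8.232849e-05,0.000000e+00
276.400000,1.324587e-08,2.175312e-01,8.187039e-05,0.000000e+00
284.300000,1.211016e-08,2.153364e-01,8.093700e-05,0.000000e+00
296.423499,1.060797e-08,2.120916e-01,7.974219e-05,0.000000e+00
302.850000,9.912218e-09,2.104289e-01,7.920735e-05,0.000000e+00
321.968169,8.173333e-09,2.057005e-01,7.793518e-05,0.000000e+00
344.280000,6.626103e-09,2.005578e-01,7.690166e-05,0.000000e+00
349.714183,6.310172e-09,1.993612e-01,7.670474e-05,0.000000e+00
356.010000,5.969105e-09,1.980007e-01,7.649830e-05,0.000000e+00
364.490000,5.548024e-09,1.962102e-01,7.625285e-05,0.000000e+00
379.851245,4.882166e-09,1.930835e-01,7.588805e-05,0.000000e+00
383.850000,4.726781e-09,1.922931e-01,7.580737e-05,0.000000e+00
411.100000,3.827954e-09,1.871454e-01,7.537775e-05,0.000000e+00
412.585406,3.785901e-09,1.868761e-01,7.535931e-05,0.000000e+00
443.900000,3.028977e-09,1.814472e-01,7.505596e-05,0.000000e+00
448.140475,2.942851e-09,1.807463e-01,7.502507e-05,0.000000e+00
486.759547,2.293338e-09,1.747004e-01,7.481849e-05,0.000000e+00
487.020000,2.289660e-09,1.746615e-01,7.481746e-05,0.000000e+00
511.000000,1.983052e-09,1.711872e-01,7.473736e-05,0.000000e+00
528.706666,1.791957e-09,1.687436e-01,7.469345e-05,0.000000e+00
574.268631,1.404126e-09,1.628804e-01,7.461921e-05,0.000000e+00
623.756956,1.103476e-09,1.571145e-01,7.457589e-05,0.000000e+00
636.990000,1.038481e-09,1.556660e-01,7.456820e-05,0.000000e+00
661.660000,9.308956e-10,1.530608e-01,7.455677e-05,0.000000e+00
677.510000,8.698757e-10,1.514487e-01,7.455102e-05,0.000000e+00
722.900000,7.234215e-10,1.470761e-01,7.453932e-05,0.000000e+00
735.895281,6.879344e-10,1.458859e-01,7.453693e-05,0.000000e+00
778.900000,5.866335e-10,1.421246e-01,7.453104e-05,0.000000e+00
799.311987,5.458699e-10,1.404281e-01,7.452905e-05,0.000000e+00
815.770000,5.158819e-10,1.390988e-01,7.452772e-05,0.000000e+00
867.380000,4.357650e-10,1.351375e-01,7.452473e-05,0.000000e+00
868.193708,4.346488e-10,1.350774e-01,7.452469e-05,0.000000e+00
943.011398,3.473344e-10,1.298356e-01,7.452231e-05,0.000000e+00
964.060000,3.273483e-10,1.284544e-01,7.452188e-05,0.000000e+00
1024.276598,2.785907e-10,1.247043e-01,7.452101e-05,3.886684e-07
1085.870000,2.389464e-10,1.211471e-01,7.452047e-05,1.089441e-05
1112.070000,2.245552e-10,1.197110e-01,7.452031e-05,1.536324e-05
1112.544928,2.243062e-10,1.196854e-01,7.452031e-05,1.544425e-05
1173.230000,1.955510e-10,1.165208e-01,7.452004e-05,2.579506e-05
1208.419894,1.813068e-10,1.147804e-01,7.451993e-05,3.179726e-05
1212.950000,1.795854e-10,1.145611e-01,7.451992e-05,3.256994e-05
1299.140000,1.509731e-10,1.105799e-01,7.451975e-05,4.727103e-05
1312.557006,1.471373e-10,1.099909e-01,7.451973e-05,4.955952e-05
1332.490000,1.417022e-10,1.091302e-01,7.451971e-05,5.295941e-05
1368.630000,1.325866e-10,1.076117e-01,7.451967e-05,5.912366e-05
1408.010000,1.236213e-10,1.060155e-01,7.451964e-05,6.584055e-05
1425.668265,1.198949e-10,1.053186e-01,7.451963e-05,6.885245e-05
1548.527030,9.810141e-11,1.007650e-01,7.451957e-05,8.980799e-05
1596.210000,9.123582e-11,9.912438e-02,7.451956e-05,9.794108e-05
1681.973304,8.060622e-11,9.633154e-02,7.451954e-05,1.125694e-04
1826.919480,6.651149e-11,9.201968e-02,7.451953e-05,1.372923e-04
1984.356575,5.511497e-11,8.783066e-02,7.451952e-05,1.641457e-04
2155.361011,4.586600e-11,8.376557e-02,7.451952e-05,1.933133e-04
2341.101971,3.833169e-11,7.982531e-02,7.451951e-05,2.249944e-04
2521.400000,3.274731e-11,7.639568e-02,7.451951e-05,2.557471e-04
2542.849393,3.217079e-11,7.601055e-02,7.451951e-05,2.594056e-04
2754.010000,2.727432e-11,7.244856e-02,7.451951e-05,2.954224e-04
2761.982653,2.711359e-11,7.232169e-02,7.451951e-05,2.967823e-04
3000.000000,2.294631e-11,6.875888e-02,7.451951e-05,3.373800e-04
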
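# element=W Z=74 A=183.8400 k_edge_keV=69.5250 l3_edge_keV=10.2068
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,2.353163e-17,1.552522e-01,4.306719e+00,0.000000e+00
10.206800,2.213604e-17,1.551342e-01,4.255697e+00,0.000000e+00
10.206800,4.853746e+02,1.551342e-01,4.255697e+00,0.000000e+00
10.861763,4.113194e+02,1.547618e-01,4.094853e+00,0.000000e+00
11.797789,3.295750e+02,1.542337e-01,3.868517e+00,0.000000e+00
12.814478,2.636137e+02,1.536655e-01,3.629886e+00,0.000000e+00
13.918782,2.104866e+02,1.530546e-01,3.381833e+00,0.000000e+00
15.118251,1.677790e+02,1.523983e-01,3.127829e+00,0.000000e+00
16.421085,1.335150e+02,1.516937e-01,2.871766e+00,0.000000e+00
17.836193,1.060788e+02,1.509383e-01,2.617726e+00,0.000000e+00
19.373249,8.415154e+01,1.501289e-01,2.369694e+00,0.000000e+00
21.042763,6.665931e+01,1.492628e-01,2.131287e+00,0.000000e+00
22.856150,5.272958e+01,1.483370e-01,1.905516e+00,0.000000e+00
24.825808,4.165542e+01,1.473487e-01,1.694632e+00,0.000000e+00
26.340000,3.515644e+01,1.466009e-01,1.553571e+00,0.000000e+00
26.965203,3.286553e+01,1.462950e-01,1.500066e+00,0.000000e+00
29.288964,2.589936e+01,1.451732e-01,1.322465e+00,0.000000e+00
30.970000,2.203765e+01,1.443760e-01,1.212165e+00,0.000000e+00
31.812977,2.038654e+01,1.439807e-01,1.161803e+00,0.000000e+00
34.554501,1.602987e+01,1.427150e-01,1.017534e+00,0.000000e+00
37.532278,1.259140e+01,1.413739e-01,8.887558e-01,0.000000e+00
40.766670,9.881019e+00,1.399554e-01,7.743558e-01,0.000000e+00
44.279789,7.747081e+00,1.384580e-01,6.731295e-01,0.000000e+00
48.095656,6.068885e+00,1.368803e-01,5.838618e-01,0.000000e+00
52.240360,4.750508e+00,1.352215e-01,5.053782e-01,0.000000e+00
53.160000,4.510699e+00,1.348609e-01,4.900826e-01,0.000000e+00
56.742239,3.715848e+00,1.334813e-01,4.365716e-01,0.000000e+00
59.540000,3.219662e+00,1.324307e-01,4.005567e-01,0.000000e+00
61.632073,2.904620e+00,1.316599e-01,3.764145e-01,0.000000e+00
66.943295,2.269145e+00,1.297579e-01,3.239609e-01,0.000000e+00
69.525000,2.026277e+00,1.288608e-01,3.022801e-01,0.000000e+00
69.525000,1.228567e+01,1.288608e-01,3.022801e-01,0.000000e+00
72.712218,1.090812e+01,1.277768e-01,2.783445e-01,0.000000e+00
78.978285,8.753334e+00,1.257186e-01,2.387755e-01,0.000000e+00
80.190000,8.404732e+00,1.253313e-01,2.320886e-01,0.000000e+00
80.997000,8.182933e+00,1.250752e-01,2.277874e-01,0.000000e+00
85.784339,7.017538e+00,1.235858e-01,2.045361e-01,0.000000e+00
93.176913,5.620818e+00,1.213817e-01,1.749770e-01,0.000000e+00
101.206551,4.498248e+00,1.191104e-01,1.495133e-01,0.000000e+00
109.928154,3.597089e+00,1.167762e-01,1.276213e-01,0.000000e+00
119.401351,2.874513e+00,1.143844e-01,1.088339e-01,0.000000e+00
121.780000,2.724499e+00,1.138057e-01,1.047629e-01,0.000000e+00
129.690913,2.295768e+00,1.119405e-01,9.273723e-02,0.000000e+00
140.510000,1.845432e+00,1.095276e-01,7.935765e-02,0.000000e+00
140.867192,1.832697e+00,1.094505e-01,7.896607e-02,0.000000e+00
153.006600,1.462521e+00,1.069209e-01,6.719986e-02,0.000000e+00
160.610000,1.281041e+00,1.054210e-01,6.111593e-02,0.000000e+00
166.192137,1.166846e+00,1.043583e-01,5.715842e-02,0.000000e+00
180.513955,9.308463e-01,1.017694e-01,4.859785e-02,0.000000e+00
196.069973,7.425896e-01,9.916110e-02,4.130661e-02,0.000000e+00
212.966551,5.924902e-01,9.654005e-02,3.510182e-02,0.000000e+00
223.200000,5.212557e-01,9.504876e-02,3.200152e-02,0.000000e+00
231.319213,4.728583e-01,9.391282e-02,2.982584e-02,0.000000e+00
244.700000,4.056896e-01,9.212526e-02,2.669751e-02,0.000000e+00
251.253438,3.775338e-01,9.128569e-02,2.534313e-02,0.000000e+00
272.905521,3.015882e-01,8.866455e-02,2.153743e-02,0.000000e+00
276.400000,2.913570e-01,8.826200e-02,2.100523e-02,0.000000e+00
284.300000,2.699310e-01,8.737146e-02,1.987345e-02,0.000000e+00
296.423499,2.410831e-01,8.605491e-02,1.830923e-02,0.000000e+00
302.850000,2.275044e-01,8.538030e-02,1.755521e-02,0.000000e+00
321.968169,1.928745e-01,8.346177e-02,1.557350e-02,0.000000e+00
344.280000,1.610807e-01,8.137513e-02,1.366724e-02,0.000000e+00
349.714183,1.544548e-01,8.088963e-02,1.325776e-02,0.000000e+00
356.010000,1.472445e-01,8.033760e-02,1.280686e-02,0.000000e+00
364.490000,1.382554e-01,7.961114e-02,1.223651e-02,0.000000e+00
379.851245,1.238257e-01,7.834251e-02,1.130029e-02,0.000000e+00
383.850000,1.204171e-01,7.802180e-02,1.107513e-02,0.000000e+00
411.100000,1.003506e-01,7.593314e-02,9.714945e-03,0.000000e+00
412.585406,9.939584e-02,7.582388e-02,9.648630e-03,0.000000e+00
443.900000,8.192442e-02,7.362112e-02,8.406126e-03,0.000000e+00
448.140475,7.989881e-02,7.333675e-02,8.258248e-03,0.000000e+00
486.759547,6.432714e-02,7.088365e-02,7.091392e-03,0.000000e+00
487.020000,6.423732e-02,7.086790e-02,7.084497e-03,0.000000e+00
511.000000,5.667476e-02,6.945820e-02,6.496614e-03,0.000000e+00
528.706666,5.187974e-02,6.846674e-02,6.116051e-03,0.000000e+00
574.268631,4.191977e-02,6.608778e-02,5.305052e-03,0.000000e+00
623.756956,3.394107e-02,6.374827e-02,4.635253e-03,0.000000e+00
636.990000,3.218016e-02,6.316056e-02,4.485196e-03,0.000000e+00
661.660000,2.923272e-02,6.210353e-02,4.232515e-03,0.000000e+00
677.510000,2.754133e-02,6.144943e-02,4.086809e-03,0.000000e+00
722.900000,2.341598e-02,5.967525e-02,3.730268e-03,0.000000e+00
735.895281,2.240080e-02,5.919234e-02,3.642528e-03,0.000000e+00
778.900000,1.946454e-02,5.766623e-02,3.389739e-03,0.000000e+00
799.311987,1.826529e-02,5.697787e-02,3.287309e-03,0.000000e+00
815.770000,1.737587e-02,5.643853e-02,3.211835e-03,0.000000e+00
867.380000,1.496657e-02,5.483123e-02,3.010486e-03,0.000000e+00
868.193708,1.493264e-02,5.480685e-02,3.007692e-03,0.000000e+00
943.011398,1.224206e-02,5.268001e-02,2.791529e-03,0.000000e+00
964.060000,1.161515e-02,5.211961e-02,2.743104e-03,0.000000e+00
1024.276598,1.006556e-02,5.059805e-02,2.627798e-03,1.166979e-05
1085.870000,8.781594e-03,4.915474e-02,2.538277e-03,3.271054e-04
1112.070000,8.309409e-03,4.857205e-02,2.507067e-03,4.612823e-04
1112.544928,8.301208e-03,4.856165e-02,2.506534e-03,4.637145e-04
1173.230000,7.346607e-03,4.727763e-02,2.446856e-03,7.744984e-04
1208.419894,6.867749e-03,4.657147e-02,2.418857e-03,9.547148e-04
1212.950000,6.809592e-03,4.648249e-02,2.415553e-03,9.779147e-04
1299.140000,5.832860e-03,4.486714e-02,2.363548e-03,1.419316e-03
1312.557006,5.700371e-03,4.462817e-02,2.357038e-03,1.488028e-03
1332.490000,5.511963e-03,4.427895e-02,2.348023e-03,1.590110e-03
1368.630000,5.194089e-03,4.366281e-02,2.333484e-03,1.775192e-03
1408.010000,4.879024e-03,4.301516e-02,2.319946e-03,1.976867e-03
1425.668265,4.747316e-03,4.273240e-02,2.314556e-03,2.067299e-03
1548.527030,3.967206e-03,4.088480e-02,2.286103e-03,2.696491e-03
1596.210000,3.717589e-03,4.021914e-02,2.278326e-03,2.940687e-03
1681.973304,3.326922e-03,3.908595e-02,2.267520e-03,3.379903e-03
1826.919480,2.799919e-03,3.733644e-02,2.255675e-03,4.122210e-03
1984.356575,2.364888e-03,3.563677e-02,2.248296e-03,4.928486e-03
2155.361011,2.004697e-03,3.398739e-02,2.243797e-03,5.804243e-03
2341.101971,1.705552e-03,3.238865e-02,2.241108e-03,6.755470e-03
2521.400000,1.479843e-03,3.099710e-02,2.239655e-03,7.678823e-03
2542.849393,1.456322e-03,3.084083e-02,2.239530e-03,7.788671e-03
2754.010000,1.254689e-03,2.939558e-02,2.238642e-03,8.870078e-03
2761.982653,1.248009e-03,2.934410e-02,2.238618e-03,8.910908e-03
3000.000000,1.073328e-03,2.789851e-02,2.238100e-03,1.012986e-02
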
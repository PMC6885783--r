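# element=N Z=7 A=14.0070 k_edge_keV=0.4099 l3_edge_keV=NA
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,3.672732e+00,1.927520e-01,2.366030e-01,0.000000e+00
10.861763,2.808644e+00,1.921432e-01,2.109508e-01,0.000000e+00
11.797789,2.146627e+00,1.914876e-01,1.871445e-01,0.000000e+00
12.814478,1.639759e+00,1.907821e-01,1.653041e-01,0.000000e+00
13.918782,1.251925e+00,1.900236e-01,1.454635e-01,0.000000e+00
15.118251,9.553503e-01,1.892087e-01,1.275860e-01,0.000000e+00
16.421085,7.286934e-01,1.883341e-01,1.115839e-01,0.000000e+00
17.836193,5.555675e-01,1.873961e-01,9.733663e-02,0.000000e+00
19.373249,4.233999e-01,1.863912e-01,8.470667e-02,0.000000e+00
21.042763,3.225516e-01,1.853159e-01,7.355092e-02,0.000000e+00
22.856150,2.456376e-01,1.841666e-01,6.372855e-02,0.000000e+00
24.825808,1.870041e-01,1.829395e-01,5.510540e-02,0.000000e+00
26.340000,1.537948e-01,1.820110e-01,4.959627e-02,0.000000e+00
26.965203,1.423252e-01,1.816313e-01,4.755613e-02,0.000000e+00
29.288964,1.082930e-01,1.802386e-01,4.096492e-02,0.000000e+00
30.970000,9.003680e-02,1.792488e-01,3.700281e-02,0.000000e+00
31.812977,8.238009e-02,1.787580e-01,3.522551e-02,0.000000e+00
34.554501,6.265590e-02,1.771866e-01,3.024077e-02,0.000000e+00
37.532278,4.764700e-02,1.755215e-01,2.592231e-02,0.000000e+00
40.766670,3.622923e-02,1.737604e-01,2.218998e-02,0.000000e+00
44.279789,2.754544e-02,1.719013e-01,1.897143e-02,0.000000e+00
48.095656,2.094234e-02,1.699425e-01,1.620168e-02,0.000000e+00
52.240360,1.592225e-02,1.678831e-01,1.382268e-02,0.000000e+00
53.160000,1.502728e-02,1.674354e-01,1.336542e-02,0.000000e+00
56.742239,1.210616e-02,1.657226e-01,1.178279e-02,0.000000e+00
59.540000,1.032144e-02,1.644182e-01,1.073299e-02,0.000000e+00
61.632073,9.205587e-03,1.634612e-01,1.003640e-02,0.000000e+00
66.943295,7.001022e-03,1.610999e-01,8.543332e-03,0.000000e+00
72.712218,5.325478e-03,1.586402e-01,7.268419e-03,0.000000e+00
78.978285,4.051974e-03,1.560848e-01,6.180985e-03,0.000000e+00
80.190000,3.853175e-03,1.556039e-01,5.998958e-03,0.000000e+00
80.997000,3.727803e-03,1.552860e-01,5.882143e-03,0.000000e+00
85.784339,3.083972e-03,1.534369e-01,5.254374e-03,0.000000e+00
93.176913,2.348098e-03,1.507005e-01,4.465510e-03,0.000000e+00
101.206551,1.788594e-03,1.478805e-01,3.794471e-03,0.000000e+00
109.928154,1.363094e-03,1.449825e-01,3.224108e-03,0.000000e+00
119.401351,1.039416e-03,1.420130e-01,2.739695e-03,0.000000e+00
121.780000,9.743943e-04,1.412945e-01,2.635372e-03,0.000000e+00
129.690913,7.931119e-04,1.389787e-01,2.328615e-03,0.000000e+00
140.510000,6.106438e-04,1.359831e-01,1.989945e-03,0.000000e+00
140.867192,6.056131e-04,1.358874e-01,1.980078e-03,0.000000e+00
153.006600,4.628152e-04,1.327467e-01,1.684875e-03,0.000000e+00
160.610000,3.954284e-04,1.308846e-01,1.533306e-03,0.000000e+00
166.192137,3.540047e-04,1.295651e-01,1.435159e-03,0.000000e+00
180.513955,2.710437e-04,1.263509e-01,1.224258e-03,0.000000e+00
196.069973,2.077493e-04,1.231126e-01,1.046503e-03,0.000000e+00
212.966551,1.594240e-04,1.198585e-01,8.970847e-04,0.000000e+00
223.200000,1.372509e-04,1.180070e-01,8.232828e-04,0.000000e+00
231.319213,1.224974e-04,1.165967e-01,7.719268e-04,0.000000e+00
244.700000,1.024775e-04,1.143773e-01,6.988623e-04,0.000000e+00
251.253438,9.425557e-05,1.133350e-01,6.675718e-04,0.000000e+00
272.905521,7.263453e-05,1.100807e-01,5.810805e-04,0.000000e+00
276.400000,6.978894e-05,1.095809e-01,5.691892e-04,0.000000e+00
284.300000,6.388585e-05,1.084753e-01,5.441023e-04,0.000000e+00
296.423499,5.606434e-05,1.068407e-01,5.099424e-04,0.000000e+00
302.850000,5.243607e-05,1.060032e-01,4.937200e-04,0.000000e+00
321.968169,4.335020e-05,1.036212e-01,4.519943e-04,0.000000e+00
344.280000,3.524136e-05,1.010306e-01,4.133986e-04,0.000000e+00
349.714183,3.358236e-05,1.004278e-01,4.053495e-04,0.000000e+00
356.010000,3.179001e-05,9.974246e-02,3.965993e-04,0.000000e+00
364.490000,2.957513e-05,9.884053e-02,3.857141e-04,0.000000e+00
379.851245,2.606776e-05,9.726547e-02,3.683384e-04,0.000000e+00
383.850000,2.524833e-05,9.686729e-02,3.642598e-04,0.000000e+00
411.100000,2.050054e-05,9.427414e-02,3.405716e-04,0.000000e+00
412.585406,2.027806e-05,9.413849e-02,3.394625e-04,0.000000e+00
443.900000,1.626739e-05,9.140366e-02,3.196014e-04,0.000000e+00
448.140475,1.581025e-05,9.105061e-02,3.173642e-04,0.000000e+00
486.759547,1.235665e-05,8.800499e-02,3.008124e-04,0.000000e+00
487.020000,1.233706e-05,8.798543e-02,3.007209e-04,0.000000e+00
511.000000,1.070251e-05,8.623523e-02,2.932195e-04,0.000000e+00
528.706666,9.682186e-06,8.500429e-02,2.887008e-04,0.000000e+00
574.268631,7.607078e-06,8.205071e-02,2.800543e-04,0.000000e+00
623.756956,5.993704e-06,7.914611e-02,2.740368e-04,0.000000e+00
636.990000,5.644277e-06,7.841645e-02,2.728411e-04,0.000000e+00
661.660000,5.065311e-06,7.710411e-02,2.709612e-04,0.000000e+00
677.510000,4.736596e-06,7.629202e-02,2.699554e-04,0.000000e+00
722.900000,3.946532e-06,7.408929e-02,2.677449e-04,0.000000e+00
735.895281,3.754834e-06,7.348973e-02,2.672570e-04,0.000000e+00
778.900000,3.206992e-06,7.159501e-02,2.659791e-04,0.000000e+00
799.311987,2.986256e-06,7.074039e-02,2.655165e-04,0.000000e+00
815.770000,2.823756e-06,7.007077e-02,2.651963e-04,0.000000e+00
867.380000,2.389102e-06,6.807525e-02,2.644298e-04,0.000000e+00
868.193708,2.383041e-06,6.804498e-02,2.644201e-04,0.000000e+00
943.011398,1.908352e-06,6.540442e-02,2.637447e-04,0.000000e+00
964.060000,1.799532e-06,6.470865e-02,2.636146e-04,0.000000e+00
1024.276598,1.533765e-06,6.281958e-02,2.633372e-04,1.370537e-06
1085.870000,1.317330e-06,6.102765e-02,2.631539e-04,3.841627e-05
1112.070000,1.238677e-06,6.030421e-02,2.630968e-04,5.417443e-05
1112.544928,1.237315e-06,6.029130e-02,2.630959e-04,5.446008e-05
1173.230000,1.080005e-06,5.869713e-02,2.629970e-04,9.095949e-05
1208.419894,1.001997e-06,5.782041e-02,2.629554e-04,1.121247e-04
1212.950000,9.925668e-07,5.770994e-02,2.629507e-04,1.148493e-04
1299.140000,8.356766e-07,5.570441e-02,2.628827e-04,1.666888e-04
1312.557006,8.146234e-07,5.540772e-02,2.628750e-04,1.747586e-04
1332.490000,7.847835e-07,5.497415e-02,2.628646e-04,1.867474e-04
1368.630000,7.347120e-07,5.420919e-02,2.628487e-04,2.084840e-04
1408.010000,6.854354e-07,5.340511e-02,2.628348e-04,2.321694e-04
1425.668265,6.649443e-07,5.305405e-02,2.628295e-04,2.427901e-04
1548.527030,5.449802e-07,5.076017e-02,2.628041e-04,3.166842e-04
1596.210000,5.071403e-07,4.993372e-02,2.627980e-04,3.453635e-04
1681.973304,4.485041e-07,4.852683e-02,2.627901e-04,3.969463e-04
1826.919480,3.706462e-07,4.635474e-02,2.627824e-04,4.841251e-04
1984.356575,3.075891e-07,4.424453e-02,2.627782e-04,5.788166e-04
2155.361011,2.563336e-07,4.219675e-02,2.627760e-04,6.816683e-04
2341.101971,2.145169e-07,4.021185e-02,2.627748e-04,7.933834e-04
2521.400000,1.834796e-07,3.848418e-02,2.627742e-04,9.018248e-04
2542.849393,1.802730e-07,3.829017e-02,2.627742e-04,9.147256e-04
2754.010000,1.530197e-07,3.649583e-02,2.627738e-04,1.041730e-03
2761.982653,1.521245e-07,3.643192e-02,2.627738e-04,1.046525e-03
3000.000000,1.288980e-07,3.463716e-02,2.627736e-04,1.189682e-03
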
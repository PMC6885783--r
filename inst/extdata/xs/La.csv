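# element=La Z=57 A=138.9050 k_edge_keV=38.9246 l3_edge_keV=5.4827
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,2.923427e+02,1.582716e-01,3.206424e+00,0.000000e+00
10.861763,2.315230e+02,1.577717e-01,3.028138e+00,0.000000e+00
11.797789,1.830809e+02,1.572333e-01,2.840304e+00,0.000000e+00
12.814478,1.445656e+02,1.566541e-01,2.645204e+00,0.000000e+00
13.918782,1.139950e+02,1.560313e-01,2.445583e+00,0.000000e+00
15.118251,8.976967e+01,1.553622e-01,2.244513e+00,0.000000e+00
16.421085,7.060252e+01,1.546440e-01,2.045199e+00,0.000000e+00
17.836193,5.546002e+01,1.538738e-01,1.850762e+00,0.000000e+00
19.373249,4.351418e+01,1.530487e-01,1.664019e+00,0.000000e+00
21.042763,3.410309e+01,1.521657e-01,1.487308e+00,0.000000e+00
22.856150,2.669866e+01,1.512220e-01,1.322362e+00,0.000000e+00
24.825808,2.088038e+01,1.502144e-01,1.170271e+00,0.000000e+00
26.340000,1.749921e+01,1.494520e-01,1.069529e+00,0.000000e+00
26.965203,1.631402e+01,1.491402e-01,1.031513e+00,0.000000e+00
29.288964,1.273436e+01,1.479966e-01,9.060423e-01,0.000000e+00
30.970000,1.076775e+01,1.471839e-01,8.286354e-01,0.000000e+00
31.812977,9.931330e+00,1.467809e-01,7.934135e-01,0.000000e+00
34.554501,7.738775e+00,1.454906e-01,6.929058e-01,0.000000e+00
37.532278,6.025491e+00,1.441234e-01,6.036402e-01,0.000000e+00
38.924600,5.395100e+00,1.434960e-01,5.676302e-01,0.000000e+00
38.924600,3.224121e+01,1.434960e-01,5.676302e-01,0.000000e+00
40.766670,2.846697e+01,1.426773e-01,5.246689e-01,0.000000e+00
44.279789,2.276503e+01,1.411508e-01,4.550387e-01,0.000000e+00
48.095656,1.818329e+01,1.395424e-01,3.938295e-01,0.000000e+00
52.240360,1.450645e+01,1.378514e-01,3.401753e-01,0.000000e+00
53.160000,1.382880e+01,1.374838e-01,3.297374e-01,0.000000e+00
56.742239,1.155981e+01,1.360773e-01,2.932724e-01,0.000000e+00
59.540000,1.012316e+01,1.350062e-01,2.687780e-01,0.000000e+00
61.632073,9.201659e+00,1.342205e-01,2.523815e-01,0.000000e+00
66.943295,7.317093e+00,1.322815e-01,2.168255e-01,0.000000e+00
72.712218,5.813028e+00,1.302619e-01,1.859873e-01,0.000000e+00
78.978285,4.614179e+00,1.281636e-01,1.593060e-01,0.000000e+00
80.190000,4.421616e+00,1.277687e-01,1.548038e-01,0.000000e+00
80.997000,4.299318e+00,1.275077e-01,1.519089e-01,0.000000e+00
85.784339,3.659759e+00,1.259893e-01,1.362745e-01,0.000000e+00
93.176913,2.900785e+00,1.237424e-01,1.164363e-01,0.000000e+00
101.206551,2.297858e+00,1.214269e-01,9.938233e-02,0.000000e+00
109.928154,1.819348e+00,1.190473e-01,8.474822e-02,0.000000e+00
119.401351,1.439906e+00,1.166090e-01,7.221100e-02,0.000000e+00
121.780000,1.361674e+00,1.160191e-01,6.949702e-02,0.000000e+00
129.690913,1.139254e+00,1.141175e-01,6.148584e-02,0.000000e+00
140.510000,9.077068e-01,1.116578e-01,5.258314e-02,0.000000e+00
140.867192,9.011934e-01,1.115792e-01,5.232275e-02,0.000000e+00
153.006600,7.128048e-01,1.090004e-01,4.450330e-02,0.000000e+00
160.610000,6.211764e-01,1.074713e-01,4.046371e-02,0.000000e+00
166.192137,5.637986e-01,1.063879e-01,3.783738e-02,0.000000e+00
180.513955,4.459901e-01,1.037487e-01,3.216011e-02,0.000000e+00
196.069973,3.528767e-01,1.010896e-01,2.732902e-02,0.000000e+00
212.966551,2.792979e-01,9.841760e-02,2.322127e-02,0.000000e+00
223.200000,2.446209e-01,9.689731e-02,2.117012e-02,0.000000e+00
231.319213,2.211624e-01,9.573928e-02,1.973128e-02,0.000000e+00
244.700000,1.887564e-01,9.391695e-02,1.766340e-02,0.000000e+00
251.253438,1.752297e-01,9.306105e-02,1.676851e-02,0.000000e+00
272.905521,1.389354e-01,9.038894e-02,1.425543e-02,0.000000e+00
276.400000,1.340695e-01,8.997856e-02,1.390420e-02,0.000000e+00
284.300000,1.238992e-01,8.907070e-02,1.315745e-02,0.000000e+00
296.423499,1.102515e-01,8.772854e-02,1.212586e-02,0.000000e+00
302.850000,1.038469e-01,8.704081e-02,1.162882e-02,0.000000e+00
321.968169,8.757525e-02,8.508497e-02,1.032334e-02,0.000000e+00
344.280000,7.272413e-02,8.295775e-02,9.069010e-03,0.000000e+00
349.714183,6.964100e-02,8.246281e-02,8.799809e-03,0.000000e+00
356.010000,6.629101e-02,8.190005e-02,8.503488e-03,0.000000e+00
364.490000,6.212230e-02,8.115945e-02,8.128858e-03,0.000000e+00
379.851245,5.544952e-02,7.986615e-02,7.514434e-03,0.000000e+00
383.850000,5.387691e-02,7.953920e-02,7.366778e-03,0.000000e+00
411.100000,4.465000e-02,7.740992e-02,6.475924e-03,0.000000e+00
412.585406,4.421237e-02,7.729854e-02,6.432548e-03,0.000000e+00
443.900000,3.622977e-02,7.505293e-02,5.621141e-03,0.000000e+00
448.140475,3.530760e-02,7.476304e-02,5.524761e-03,0.000000e+00
486.759547,2.824471e-02,7.226223e-02,4.766151e-03,0.000000e+00
487.020000,2.820411e-02,7.224617e-02,4.761679e-03,0.000000e+00
511.000000,2.479272e-02,7.080906e-02,4.381129e-03,0.000000e+00
528.706666,2.263693e-02,6.979831e-02,4.135563e-03,0.000000e+00
574.268631,1.817927e-02,6.737308e-02,3.614975e-03,0.000000e+00
623.756956,1.463124e-02,6.498807e-02,3.188924e-03,0.000000e+00
636.990000,1.385137e-02,6.438893e-02,3.094135e-03,0.000000e+00
661.660000,1.254887e-02,6.331135e-02,2.935206e-03,0.000000e+00
677.510000,1.180316e-02,6.264453e-02,2.844007e-03,0.000000e+00
722.900000,9.990164e-03,6.083584e-02,2.622519e-03,0.000000e+00
735.895281,9.545389e-03,6.034353e-02,2.568442e-03,0.000000e+00
778.900000,8.262316e-03,5.878775e-02,2.413806e-03,0.000000e+00
799.311987,7.739832e-03,5.808600e-02,2.351718e-03,0.000000e+00
815.770000,7.352966e-03,5.753617e-02,2.306214e-03,0.000000e+00
867.380000,6.307929e-03,5.589762e-02,2.186001e-03,0.000000e+00
868.193708,6.293243e-03,5.587276e-02,2.184346e-03,0.000000e+00
943.011398,5.131953e-03,5.370456e-02,2.057715e-03,0.000000e+00
964.060000,4.862345e-03,5.313325e-02,2.029776e-03,0.000000e+00
1024.276598,4.197716e-03,5.158211e-02,1.964043e-03,9.163716e-06
1085.870000,3.649141e-03,5.011072e-02,1.913935e-03,2.568598e-04
1112.070000,3.447938e-03,4.951670e-02,1.896697e-03,3.622223e-04
1112.544928,3.444446e-03,4.950610e-02,1.896404e-03,3.641322e-04
1173.230000,3.038664e-03,4.819711e-02,1.863845e-03,6.081755e-04
1208.419894,2.835640e-03,4.747721e-02,1.848777e-03,7.496906e-04
1212.950000,2.811009e-03,4.738650e-02,1.847009e-03,7.679083e-04
1299.140000,2.398216e-03,4.573974e-02,1.819490e-03,1.114519e-03
1312.557006,2.342359e-03,4.549612e-02,1.816092e-03,1.168475e-03
1332.490000,2.262987e-03,4.514011e-02,1.811405e-03,1.248635e-03
1368.630000,2.129240e-03,4.451199e-02,1.803898e-03,1.393971e-03
1408.010000,1.996891e-03,4.385174e-02,1.796970e-03,1.552336e-03
1425.668265,1.941630e-03,4.356348e-02,1.794230e-03,1.623349e-03
1548.527030,1.615195e-03,4.167994e-02,1.779970e-03,2.117422e-03
1596.210000,1.511086e-03,4.100134e-02,1.776144e-03,2.309177e-03
1681.973304,1.348521e-03,3.984612e-02,1.770892e-03,2.654072e-03
1826.919480,1.130024e-03,3.806258e-02,1.765243e-03,3.236969e-03
1984.356575,9.504556e-04,3.632985e-02,1.761803e-03,3.870097e-03
2155.361011,8.024170e-04,3.464839e-02,1.759749e-03,4.557787e-03
2341.101971,6.799806e-04,3.301856e-02,1.758544e-03,5.304739e-03
2521.400000,5.879571e-04,3.159994e-02,1.757904e-03,6.029802e-03
2542.849393,5.783869e-04,3.144064e-02,1.757849e-03,6.116060e-03
2754.010000,4.965135e-04,2.996728e-02,1.757464e-03,6.965236e-03
2761.982653,4.938068e-04,2.991480e-02,1.757454e-03,6.997298e-03
3000.000000,4.231530e-04,2.844110e-02,1.757232e-03,7.954478e-03
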
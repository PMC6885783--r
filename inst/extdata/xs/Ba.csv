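# element=Ba Z=56 A=137.3270 k_edge_keV=37.4406 l3_edge_keV=5.2470
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,2.786117e+02,1.572817e-01,3.118393e+00,0.000000e+00
10.861763,2.204600e+02,1.567849e-01,2.943602e+00,0.000000e+00
11.797789,1.741885e+02,1.562499e-01,2.759632e+00,0.000000e+00
12.814478,1.374340e+02,1.556743e-01,2.568744e+00,0.000000e+00
13.918782,1.082876e+02,1.550554e-01,2.373650e+00,0.000000e+00
15.118251,8.521119e+01,1.543904e-01,2.177361e+00,0.000000e+00
16.421085,6.696855e+01,1.536767e-01,1.983010e+00,0.000000e+00
17.836193,5.256823e+01,1.529113e-01,1.793628e+00,0.000000e+00
19.373249,4.121689e+01,1.520914e-01,1.611939e+00,0.000000e+00
21.042763,3.228102e+01,1.512140e-01,1.440185e+00,0.000000e+00
22.856150,2.525571e+01,1.502761e-01,1.280014e+00,0.000000e+00
24.825808,1.973932e+01,1.492749e-01,1.132446e+00,0.000000e+00
26.340000,1.653554e+01,1.485173e-01,1.034760e+00,0.000000e+00
26.965203,1.541293e+01,1.482074e-01,9.979077e-01,0.000000e+00
29.288964,1.202371e+01,1.470710e-01,8.763228e-01,0.000000e+00
30.970000,1.016277e+01,1.462633e-01,8.013429e-01,0.000000e+00
31.812977,9.371558e+00,1.458628e-01,7.672323e-01,0.000000e+00
34.554501,7.298369e+00,1.445806e-01,6.699186e-01,0.000000e+00
37.440600,5.721744e+00,1.432633e-01,5.859243e-01,0.000000e+00
37.440600,3.413326e+01,1.432633e-01,5.859243e-01,0.000000e+00
37.532278,3.390938e+01,1.432219e-01,5.835159e-01,0.000000e+00
40.766670,2.712991e+01,1.417849e-01,5.070969e-01,0.000000e+00
44.279789,2.167945e+01,1.402679e-01,4.397321e-01,0.000000e+00
48.095656,1.730302e+01,1.386696e-01,3.805267e-01,0.000000e+00
52.240360,1.379370e+01,1.369892e-01,3.286392e-01,0.000000e+00
53.160000,1.314726e+01,1.366239e-01,3.185462e-01,0.000000e+00
56.742239,1.098361e+01,1.352262e-01,2.832895e-01,0.000000e+00
59.540000,9.614448e+00,1.341618e-01,2.596098e-01,0.000000e+00
61.632073,8.736597e+00,1.333810e-01,2.437602e-01,0.000000e+00
66.943295,6.942319e+00,1.314542e-01,2.093945e-01,0.000000e+00
72.712218,5.511465e+00,1.294472e-01,1.795939e-01,0.000000e+00
78.978285,4.371862e+00,1.273620e-01,1.538148e-01,0.000000e+00
80.190000,4.188901e+00,1.269696e-01,1.494653e-01,0.000000e+00
80.997000,4.072715e+00,1.267102e-01,1.466686e-01,0.000000e+00
85.784339,3.465297e+00,1.252013e-01,1.315657e-01,0.000000e+00
93.176913,2.744907e+00,1.229685e-01,1.124041e-01,0.000000e+00
101.206551,2.173037e+00,1.206674e-01,9.593402e-02,0.000000e+00
109.928154,1.719487e+00,1.183027e-01,8.180269e-02,0.000000e+00
119.401351,1.360077e+00,1.158796e-01,6.969752e-02,0.000000e+00
121.780000,1.286005e+00,1.152934e-01,6.707723e-02,0.000000e+00
129.690913,1.075480e+00,1.134038e-01,5.934298e-02,0.000000e+00
140.510000,8.564324e-01,1.109594e-01,5.074866e-02,0.000000e+00
140.867192,8.502726e-01,1.108813e-01,5.049730e-02,0.000000e+00
153.006600,6.721638e-01,1.083186e-01,4.294930e-02,0.000000e+00
160.610000,5.855767e-01,1.067991e-01,3.905017e-02,0.000000e+00
166.192137,5.313716e-01,1.057225e-01,3.651523e-02,0.000000e+00
180.513955,4.201213e-01,1.030998e-01,3.103579e-02,0.000000e+00
196.069973,3.322406e-01,1.004573e-01,2.637330e-02,0.000000e+00
212.966551,2.628345e-01,9.780204e-02,2.240914e-02,0.000000e+00
223.200000,2.301381e-01,9.629126e-02,2.042977e-02,0.000000e+00
231.319213,2.080251e-01,9.514047e-02,1.904133e-02,0.000000e+00
244.700000,1.774867e-01,9.332954e-02,1.704593e-02,0.000000e+00
251.253438,1.647429e-01,9.247899e-02,1.618244e-02,0.000000e+00
272.905521,1.305602e-01,8.982359e-02,1.375765e-02,0.000000e+00
276.400000,1.259787e-01,8.941578e-02,1.341877e-02,0.000000e+00
284.300000,1.164041e-01,8.851360e-02,1.269829e-02,0.000000e+00
296.423499,1.035584e-01,8.717983e-02,1.170303e-02,0.000000e+00
302.850000,9.753138e-02,8.649640e-02,1.122351e-02,0.000000e+00
321.968169,8.222239e-02,8.455279e-02,9.964113e-03,0.000000e+00
344.280000,6.825499e-02,8.243888e-02,8.754171e-03,0.000000e+00
349.714183,6.535601e-02,8.194704e-02,8.494514e-03,0.000000e+00
356.010000,6.220641e-02,8.138779e-02,8.208706e-03,0.000000e+00
364.490000,5.828750e-02,8.065183e-02,7.847383e-03,0.000000e+00
379.851245,5.201569e-02,7.936662e-02,7.254822e-03,0.000000e+00
383.850000,5.053778e-02,7.904171e-02,7.112429e-03,0.000000e+00
411.100000,4.186835e-02,7.692575e-02,6.253413e-03,0.000000e+00
412.585406,4.145725e-02,7.681507e-02,6.211592e-03,0.000000e+00
443.900000,3.395990e-02,7.458350e-02,5.429363e-03,0.000000e+00
448.140475,3.309398e-02,7.429542e-02,5.336462e-03,0.000000e+00
486.759547,2.646343e-02,7.181026e-02,4.605389e-03,0.000000e+00
487.020000,2.642533e-02,7.179429e-02,4.601081e-03,0.000000e+00
511.000000,2.322384e-02,7.036617e-02,4.234467e-03,0.000000e+00
528.706666,2.120112e-02,6.936175e-02,3.997954e-03,0.000000e+00
574.268631,1.701978e-02,6.695169e-02,3.496759e-03,0.000000e+00
623.756956,1.369300e-02,6.458159e-02,3.086868e-03,0.000000e+00
636.990000,1.296194e-02,6.398620e-02,2.995722e-03,0.000000e+00
661.660000,1.174114e-02,6.291536e-02,2.842951e-03,0.000000e+00
677.510000,1.104230e-02,6.225271e-02,2.755319e-03,0.000000e+00
722.900000,9.343599e-03,6.045533e-02,2.542611e-03,0.000000e+00
735.895281,8.926943e-03,5.996611e-02,2.490708e-03,0.000000e+00
778.900000,7.725178e-03,5.842005e-02,2.342372e-03,0.000000e+00
799.311987,7.235894e-03,5.772270e-02,2.282853e-03,0.000000e+00
815.770000,6.873646e-03,5.717631e-02,2.239250e-03,0.000000e+00
867.380000,5.895279e-03,5.554800e-02,2.124138e-03,0.000000e+00
868.193708,5.881532e-03,5.552330e-02,2.122554e-03,0.000000e+00
943.011398,4.794658e-03,5.336866e-02,2.001462e-03,0.000000e+00
964.060000,4.542383e-03,5.280093e-02,1.974774e-03,0.000000e+00
1024.276598,3.920584e-03,5.125948e-02,1.912037e-03,8.946639e-06
1085.870000,3.407481e-03,4.979730e-02,1.864273e-03,2.507751e-04
1112.070000,3.219319e-03,4.920699e-02,1.847857e-03,3.536417e-04
1112.544928,3.216054e-03,4.919646e-02,1.847578e-03,3.555064e-04
1173.230000,2.836630e-03,4.789565e-02,1.816597e-03,5.937686e-04
1208.419894,2.646824e-03,4.718026e-02,1.802273e-03,7.319314e-04
1212.950000,2.623797e-03,4.709012e-02,1.800593e-03,7.497175e-04
1299.140000,2.237954e-03,4.545365e-02,1.774463e-03,1.088117e-03
1312.557006,2.185752e-03,4.521156e-02,1.771239e-03,1.140795e-03
1332.490000,2.111576e-03,4.485777e-02,1.766794e-03,1.219056e-03
1368.630000,1.986595e-03,4.423358e-02,1.759678e-03,1.360949e-03
1408.010000,1.862932e-03,4.357747e-02,1.753114e-03,1.515563e-03
1425.668265,1.811302e-03,4.329101e-02,1.750519e-03,1.584893e-03
1548.527030,1.506363e-03,4.141925e-02,1.737028e-03,2.067262e-03
1596.210000,1.409129e-03,4.074489e-02,1.733412e-03,2.254476e-03
1681.973304,1.257321e-03,3.959689e-02,1.728454e-03,2.591200e-03
1826.919480,1.053327e-03,3.782451e-02,1.723127e-03,3.160289e-03
1984.356575,8.857227e-04,3.610262e-02,1.719888e-03,3.778420e-03
2155.361011,7.475835e-04,3.443168e-02,1.717956e-03,4.449818e-03
2341.101971,6.333633e-04,3.281204e-02,1.716825e-03,5.179076e-03
2521.400000,5.475352e-04,3.140230e-02,1.716224e-03,5.886963e-03
2542.849393,5.386104e-04,3.124399e-02,1.716173e-03,5.971178e-03
2754.010000,4.622678e-04,2.977984e-02,1.715812e-03,6.800238e-03
2761.982653,4.597443e-04,2.972769e-02,1.715802e-03,6.831541e-03
3000.000000,3.938789e-04,2.826321e-02,1.715594e-03,7.766046e-03
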
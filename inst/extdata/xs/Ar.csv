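# element=Ar Z=18 A=39.9480 k_edge_keV=3.2060 l3_edge_keV=0.2484
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,7.849862e+01,1.737895e-01,8.028122e-01,0.000000e+00
10.861763,6.134703e+01,1.732405e-01,7.333590e-01,0.000000e+00
11.797789,4.789373e+01,1.726494e-01,6.652241e-01,0.000000e+00
12.814478,3.735350e+01,1.720134e-01,5.994298e-01,0.000000e+00
13.918782,2.910483e+01,1.713295e-01,5.368510e-01,0.000000e+00
15.118251,2.265655e+01,1.705948e-01,4.781654e-01,0.000000e+00
16.421085,1.762102e+01,1.698062e-01,4.238296e-01,0.000000e+00
17.836193,1.369274e+01,1.689605e-01,3.740813e-01,0.000000e+00
19.373249,1.063128e+01,1.680545e-01,3.289642e-01,0.000000e+00
21.042763,8.247668e+00,1.670850e-01,2.883675e-01,0.000000e+00
22.856150,6.393535e+00,1.660486e-01,2.520699e-01,0.000000e+00
24.825808,4.952563e+00,1.649423e-01,2.197819e-01,0.000000e+00
26.340000,4.122920e+00,1.641052e-01,1.989416e-01,0.000000e+00
26.965203,3.833656e+00,1.637628e-01,1.911802e-01,0.000000e+00
29.288964,2.965556e+00,1.625071e-01,1.659332e-01,0.000000e+00
30.970000,2.492694e+00,1.616147e-01,1.506210e-01,0.000000e+00
31.812977,2.292583e+00,1.611722e-01,1.437165e-01,0.000000e+00
34.554501,1.771277e+00,1.597553e-01,1.242228e-01,0.000000e+00
37.532278,1.367755e+00,1.582541e-01,1.071657e-01,0.000000e+00
40.766670,1.055621e+00,1.566663e-01,9.228094e-02,0.000000e+00
44.279789,8.143381e-01,1.549900e-01,7.932629e-02,0.000000e+00
48.095656,6.279403e-01,1.532240e-01,6.808054e-02,0.000000e+00
52.240360,4.840268e-01,1.513671e-01,5.834248e-02,0.000000e+00
53.160000,4.581263e-01,1.509635e-01,5.646193e-02,0.000000e+00
56.742239,3.729748e-01,1.494192e-01,4.992984e-02,0.000000e+00
59.540000,3.204207e-01,1.482431e-01,4.557634e-02,0.000000e+00
61.632073,2.873236e-01,1.473802e-01,4.267824e-02,0.000000e+00
66.943295,2.212934e-01,1.452512e-01,3.644017e-02,0.000000e+00
72.712218,1.704104e-01,1.430336e-01,3.108397e-02,0.000000e+00
78.978285,1.312140e-01,1.407295e-01,2.649271e-02,0.000000e+00
80.190000,1.250457e-01,1.402959e-01,2.572205e-02,0.000000e+00
80.997000,1.211480e-01,1.400093e-01,2.522716e-02,0.000000e+00
85.784339,1.010295e-01,1.383421e-01,2.256310e-02,0.000000e+00
93.176913,7.779095e-02,1.358749e-01,1.920435e-02,0.000000e+00
101.206551,5.990364e-02,1.333323e-01,1.633698e-02,0.000000e+00
109.928154,4.613732e-02,1.307194e-01,1.389174e-02,0.000000e+00
119.401351,3.554350e-02,1.280420e-01,1.180851e-02,0.000000e+00
121.780000,3.339994e-02,1.273943e-01,1.135900e-02,0.000000e+00
129.690913,2.739124e-02,1.253063e-01,1.003525e-02,0.000000e+00
140.510000,2.128680e-02,1.226053e-01,8.569847e-03,0.000000e+00
140.867192,2.111756e-02,1.225190e-01,8.527080e-03,0.000000e+00
153.006600,1.628904e-02,1.196874e-01,7.245371e-03,0.000000e+00
160.610000,1.399153e-02,1.180084e-01,6.585300e-03,0.000000e+00
166.192137,1.257208e-02,1.168188e-01,6.156973e-03,0.000000e+00
180.513955,9.710043e-03,1.139208e-01,5.233492e-03,0.000000e+00
196.069973,7.505547e-03,1.110010e-01,4.450657e-03,0.000000e+00
212.966551,5.806803e-03,1.080670e-01,3.787761e-03,0.000000e+00
223.200000,5.021764e-03,1.063977e-01,3.457941e-03,0.000000e+00
231.319213,4.497113e-03,1.051261e-01,3.227165e-03,0.000000e+00
244.700000,3.781802e-03,1.031251e-01,2.896516e-03,0.000000e+00
251.253438,3.486767e-03,1.021853e-01,2.753871e-03,0.000000e+00
272.905521,2.706806e-03,9.925121e-02,2.355144e-03,0.000000e+00
276.400000,2.603653e-03,9.880059e-02,2.299682e-03,0.000000e+00
284.300000,2.389246e-03,9.780372e-02,2.182031e-03,0.000000e+00
296.423499,2.104216e-03,9.632997e-02,2.020182e-03,0.000000e+00
302.850000,1.971597e-03,9.557480e-02,1.942529e-03,0.000000e+00
321.968169,1.638246e-03,9.342720e-02,1.739827e-03,0.000000e+00
344.280000,1.339011e-03,9.109141e-02,1.547277e-03,0.000000e+00
349.714183,1.277559e-03,9.054795e-02,1.506312e-03,0.000000e+00
356.010000,1.211070e-03,8.993001e-02,1.461395e-03,0.000000e+00
364.490000,1.128760e-03,8.911680e-02,1.404895e-03,0.000000e+00
379.851245,9.980578e-04,8.769670e-02,1.313027e-03,0.000000e+00
383.850000,9.674536e-04,8.733769e-02,1.291117e-03,0.000000e+00
411.100000,7.895647e-04,8.499965e-02,1.160593e-03,0.000000e+00
412.585406,7.812030e-04,8.487735e-02,1.154321e-03,0.000000e+00
443.900000,6.300190e-04,8.241156e-02,1.038779e-03,0.000000e+00
448.140475,6.127280e-04,8.209324e-02,1.025311e-03,0.000000e+00
486.759547,4.816484e-04,7.934725e-02,9.217319e-04,0.000000e+00
487.020000,4.809024e-04,7.932961e-02,9.211359e-04,0.000000e+00
511.000000,4.185464e-04,7.775159e-02,8.711638e-04,0.000000e+00
528.706666,3.795025e-04,7.664174e-02,8.397942e-04,0.000000e+00
574.268631,2.997679e-04,7.397874e-02,7.760909e-04,0.000000e+00
623.756956,2.374135e-04,7.135988e-02,7.275323e-04,0.000000e+00
636.990000,2.238593e-04,7.070200e-02,7.172705e-04,0.000000e+00
661.660000,2.013573e-04,6.951877e-02,7.005799e-04,0.000000e+00
677.510000,1.885553e-04,6.878657e-02,6.913189e-04,0.000000e+00
722.900000,1.576992e-04,6.680054e-02,6.699117e-04,0.000000e+00
735.895281,1.501922e-04,6.625997e-02,6.649428e-04,0.000000e+00
778.900000,1.286893e-04,6.455165e-02,6.513667e-04,0.000000e+00
799.311987,1.200030e-04,6.378110e-02,6.462035e-04,0.000000e+00
815.770000,1.135995e-04,6.317736e-02,6.425339e-04,0.000000e+00
867.380000,9.643034e-05,6.137815e-02,6.333472e-04,0.000000e+00
868.193708,9.619047e-05,6.135086e-02,6.332263e-04,0.000000e+00
943.011398,7.736126e-05,5.897007e-02,6.244677e-04,0.000000e+00
964.060000,7.303162e-05,5.834275e-02,6.226789e-04,0.000000e+00
1024.276598,6.243383e-05,5.663952e-02,6.187046e-04,3.177531e-06
1085.870000,5.377550e-05,5.502387e-02,6.159214e-04,8.906647e-05
1112.070000,5.062209e-05,5.437161e-02,6.150196e-04,1.256011e-04
1112.544928,5.056748e-05,5.435997e-02,6.150045e-04,1.262633e-04
1173.230000,4.424805e-05,5.292263e-02,6.133893e-04,2.108857e-04
1208.419894,4.110772e-05,5.213216e-02,6.126840e-04,2.599562e-04
1212.950000,4.072775e-05,5.203255e-02,6.126031e-04,2.662732e-04
1299.140000,3.439560e-05,5.022433e-02,6.114009e-04,3.864609e-04
1312.557006,3.354421e-05,4.995683e-02,6.112603e-04,4.051703e-04
1332.490000,3.233676e-05,4.956591e-02,6.110696e-04,4.329658e-04
1368.630000,3.030865e-05,4.887620e-02,6.107720e-04,4.833613e-04
1408.010000,2.831016e-05,4.815123e-02,6.105067e-04,5.382747e-04
1425.668265,2.747831e-05,4.783470e-02,6.104045e-04,5.628983e-04
1548.527030,2.259810e-05,4.576649e-02,6.098995e-04,7.342187e-04
1596.210000,2.105477e-05,4.502135e-02,6.097729e-04,8.007103e-04
1681.973304,1.865899e-05,4.375286e-02,6.096065e-04,9.203030e-04
1826.919480,1.546885e-05,4.179446e-02,6.094391e-04,1.122423e-03
1984.356575,1.287639e-05,3.989184e-02,6.093447e-04,1.341961e-03
2155.361011,1.076226e-05,3.804552e-02,6.092921e-04,1.580419e-03
2341.101971,9.032034e-06,3.625589e-02,6.092632e-04,1.839425e-03
2521.400000,7.744129e-06,3.469819e-02,6.092486e-04,2.090842e-03
2542.849393,7.610871e-06,3.452326e-02,6.092473e-04,2.120752e-03
2754.010000,6.476593e-06,3.290545e-02,6.092390e-04,2.415205e-03
2761.982653,6.439280e-06,3.284782e-02,6.092388e-04,2.426322e-03
3000.000000,5.469853e-06,3.122963e-02,6.092342e-04,2.758226e-03
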
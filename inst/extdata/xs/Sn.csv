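# element=Sn Z=50 A=118.7100 k_edge_keV=29.2001 l3_edge_keV=3.9288
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,2.188480e+02,1.624534e-01,2.803332e+00,0.000000e+00
10.861763,1.722603e+02,1.619402e-01,2.638039e+00,0.000000e+00
11.797789,1.354127e+02,1.613877e-01,2.465177e+00,0.000000e+00
12.814478,1.063131e+02,1.607931e-01,2.287034e+00,0.000000e+00
13.918782,8.336567e+01,1.601538e-01,2.106256e+00,0.000000e+00
15.118251,6.529513e+01,1.594671e-01,1.925695e+00,0.000000e+00
16.421085,5.108417e+01,1.587299e-01,1.748221e+00,0.000000e+00
17.836193,3.992293e+01,1.579393e-01,1.576524e+00,0.000000e+00
19.373249,3.116790e+01,1.570924e-01,1.412930e+00,0.000000e+00
21.042763,2.430859e+01,1.561862e-01,1.259263e+00,0.000000e+00
22.856150,1.894074e+01,1.552175e-01,1.116780e+00,0.000000e+00
24.825808,1.474476e+01,1.541833e-01,9.861634e-01,0.000000e+00
26.340000,1.231711e+01,1.534008e-01,9.000180e-01,0.000000e+00
26.965203,1.146832e+01,1.530808e-01,8.675818e-01,0.000000e+00
29.200100,8.995663e+00,1.519514e-01,7.645120e-01,0.000000e+00
29.200100,5.291975e+01,1.519514e-01,7.645120e-01,0.000000e+00
29.288964,5.248689e+01,1.519069e-01,7.607894e-01,0.000000e+00
30.970000,4.512401e+01,1.510727e-01,6.950911e-01,0.000000e+00
31.812977,4.194978e+01,1.506591e-01,6.652402e-01,0.000000e+00
34.554501,3.348522e+01,1.493346e-01,5.801983e-01,0.000000e+00
37.532278,2.669446e+01,1.479313e-01,5.048312e-01,0.000000e+00
40.766670,2.125407e+01,1.464471e-01,4.382772e-01,0.000000e+00
44.279789,1.690180e+01,1.448802e-01,3.796907e-01,0.000000e+00
48.095656,1.342512e+01,1.432293e-01,3.282675e-01,0.000000e+00
52.240360,1.065189e+01,1.414936e-01,2.832571e-01,0.000000e+00
53.160000,1.014271e+01,1.411163e-01,2.745085e-01,0.000000e+00
56.742239,8.442861e+00,1.396727e-01,2.439666e-01,0.000000e+00
59.540000,7.371036e+00,1.385733e-01,2.234705e-01,0.000000e+00
61.632073,6.685595e+00,1.377668e-01,2.097600e-01,0.000000e+00
66.943295,5.289463e+00,1.357766e-01,1.800567e-01,0.000000e+00
72.712218,4.181561e+00,1.337036e-01,1.543282e-01,0.000000e+00
78.978285,3.303354e+00,1.315499e-01,1.320954e-01,0.000000e+00
80.190000,3.162758e+00,1.311446e-01,1.283466e-01,0.000000e+00
80.997000,3.073538e+00,1.308766e-01,1.259365e-01,0.000000e+00
85.784339,2.607936e+00,1.293182e-01,1.129261e-01,0.000000e+00
93.176913,2.057782e+00,1.270119e-01,9.643219e-02,0.000000e+00
101.206551,1.622927e+00,1.246352e-01,8.226694e-02,0.000000e+00
109.928154,1.279478e+00,1.221927e-01,7.012234e-02,0.000000e+00
119.401351,1.008415e+00,1.196900e-01,5.972613e-02,0.000000e+00
121.780000,9.526923e-01,1.190845e-01,5.747666e-02,0.000000e+00
129.690913,7.946177e-01,1.171327e-01,5.083880e-02,0.000000e+00
140.510000,6.306813e-01,1.146079e-01,4.346622e-02,0.000000e+00
140.867192,6.260802e-01,1.145272e-01,4.325065e-02,0.000000e+00
153.006600,4.932840e-01,1.118803e-01,3.677883e-02,0.000000e+00
160.610000,4.289143e-01,1.103108e-01,3.343681e-02,0.000000e+00
166.192137,3.886900e-01,1.091988e-01,3.126452e-02,0.000000e+00
180.513955,3.063335e-01,1.064899e-01,2.657023e-02,0.000000e+00
196.069973,2.415004e-01,1.037606e-01,2.257731e-02,0.000000e+00
212.966551,1.904683e-01,1.010179e-01,1.918364e-02,0.000000e+00
223.200000,1.664905e-01,9.945748e-02,1.748961e-02,0.000000e+00
231.319213,1.503005e-01,9.826885e-02,1.630154e-02,0.000000e+00
244.700000,1.279809e-01,9.639838e-02,1.459447e-02,0.000000e+00
251.253438,1.186817e-01,9.551986e-02,1.385589e-02,0.000000e+00
272.905521,9.378824e-02,9.277715e-02,1.178248e-02,0.000000e+00
276.400000,9.045787e-02,9.235593e-02,1.149279e-02,0.000000e+00
284.300000,8.350314e-02,9.142408e-02,1.087697e-02,0.000000e+00
296.423499,7.418410e-02,9.004646e-02,1.002648e-02,0.000000e+00
302.850000,6.981674e-02,8.934056e-02,9.616814e-03,0.000000e+00
321.968169,5.873948e-02,8.733304e-02,8.541225e-03,0.000000e+00
344.280000,4.865563e-02,8.514961e-02,7.508508e-03,0.000000e+00
349.714183,4.656576e-02,8.464160e-02,7.286988e-03,0.000000e+00
356.010000,4.429652e-02,8.406396e-02,7.043208e-03,0.000000e+00
364.490000,4.147499e-02,8.330381e-02,6.735101e-03,0.000000e+00
379.851245,3.696433e-02,8.197633e-02,6.230048e-03,0.000000e+00
383.850000,3.590237e-02,8.164074e-02,6.108733e-03,0.000000e+00
411.100000,2.968079e-02,7.945520e-02,5.377379e-03,0.000000e+00
412.585406,2.938612e-02,7.934088e-02,5.341799e-03,0.000000e+00
443.900000,2.401874e-02,7.703594e-02,4.676873e-03,0.000000e+00
448.140475,2.339967e-02,7.673838e-02,4.597988e-03,0.000000e+00
486.759547,1.866599e-02,7.417151e-02,3.978043e-03,0.000000e+00
487.020000,1.863883e-02,7.415502e-02,3.974395e-03,0.000000e+00
511.000000,1.635799e-02,7.267993e-02,3.664231e-03,0.000000e+00
528.706666,1.491877e-02,7.164248e-02,3.464474e-03,0.000000e+00
574.268631,1.194875e-02,6.915318e-02,3.042332e-03,0.000000e+00
623.756956,9.591489e-03,6.670515e-02,2.698729e-03,0.000000e+00
636.990000,9.074280e-03,6.609018e-02,2.622595e-03,0.000000e+00
661.660000,8.211308e-03,6.498413e-02,2.495268e-03,0.000000e+00
677.510000,7.717742e-03,6.429969e-02,2.422410e-03,0.000000e+00
722.900000,6.519453e-03,6.244321e-02,2.246229e-03,0.000000e+00
735.895281,6.225879e-03,6.193790e-02,2.203408e-03,0.000000e+00
778.900000,5.379966e-03,6.034101e-02,2.081474e-03,0.000000e+00
799.311987,5.035950e-03,5.962072e-02,2.032767e-03,0.000000e+00
815.770000,4.781409e-03,5.905636e-02,1.997175e-03,0.000000e+00
867.380000,4.094665e-03,5.737451e-02,1.903651e-03,0.000000e+00
868.193708,4.085023e-03,5.734900e-02,1.902370e-03,0.000000e+00
943.011398,3.323532e-03,5.512351e-02,1.804860e-03,0.000000e+00
964.060000,3.147021e-03,5.453711e-02,1.783521e-03,0.000000e+00
1024.276598,2.712403e-03,5.294498e-02,1.733631e-03,8.250732e-06
1085.870000,2.354280e-03,5.143472e-02,1.695961e-03,2.312688e-04
1112.070000,2.223083e-03,5.082501e-02,1.683091e-03,3.261340e-04
1112.544928,2.220807e-03,5.081412e-02,1.682872e-03,3.278536e-04
1173.230000,1.956490e-03,4.947054e-02,1.658715e-03,5.475828e-04
1208.419894,1.824395e-03,4.873163e-02,1.647613e-03,6.749987e-04
1212.950000,1.808376e-03,4.863852e-02,1.646314e-03,6.914014e-04
1299.140000,1.540168e-03,4.694825e-02,1.626208e-03,1.003479e-03
1312.557006,1.503915e-03,4.669820e-02,1.623742e-03,1.052059e-03
1332.490000,1.452415e-03,4.633278e-02,1.620348e-03,1.124233e-03
1368.630000,1.365682e-03,4.568806e-02,1.614929e-03,1.255089e-03
1408.010000,1.279916e-03,4.501037e-02,1.609950e-03,1.397677e-03
1425.668265,1.244124e-03,4.471449e-02,1.607988e-03,1.461614e-03
1548.527030,1.032938e-03,4.278119e-02,1.597844e-03,1.906462e-03
1596.210000,9.656808e-04,4.208465e-02,1.595146e-03,2.079113e-03
1681.973304,8.607634e-04,4.089891e-02,1.591465e-03,2.389646e-03
1826.919480,7.199706e-04,3.906825e-02,1.587541e-03,2.914469e-03
1984.356575,6.044819e-04,3.728974e-02,1.585177e-03,3.484518e-03
2155.361011,5.094475e-04,3.556385e-02,1.583779e-03,4.103693e-03
2341.101971,4.309892e-04,3.389096e-02,1.582966e-03,4.776226e-03
2521.400000,3.721173e-04,3.243486e-02,1.582538e-03,5.429051e-03
2542.849393,3.660001e-04,3.227135e-02,1.582501e-03,5.506715e-03
2754.010000,3.137128e-04,3.075906e-02,1.582245e-03,6.271288e-03
2761.982653,3.119857e-04,3.070519e-02,1.582238e-03,6.300155e-03
3000.000000,2.669386e-04,2.919255e-02,1.582092e-03,7.161971e-03
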
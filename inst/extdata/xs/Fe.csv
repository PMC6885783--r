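# element=Fe Z=26 A=55.8450 k_edge_keV=7.1120 l3_edge_keV=0.7081
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,2.246369e+02,1.795706e-01,1.352004e+00,0.000000e+00
10.861763,1.778685e+02,1.790033e-01,1.248459e+00,0.000000e+00
11.797789,1.406437e+02,1.783926e-01,1.144436e+00,0.000000e+00
12.814478,1.110614e+02,1.777354e-01,1.041595e+00,0.000000e+00
13.918782,8.758834e+01,1.770287e-01,9.415318e-01,0.000000e+00
15.118251,6.899067e+01,1.762696e-01,8.456704e-01,0.000000e+00
16.421085,5.427698e+01,1.754547e-01,7.551713e-01,0.000000e+00
17.836193,4.265227e+01,1.745809e-01,6.708771e-01,0.000000e+00
19.373249,3.348032e+01,1.736447e-01,5.932975e-01,0.000000e+00
21.042763,2.625291e+01,1.726430e-01,5.226313e-01,0.000000e+00
22.856150,2.056480e+01,1.715722e-01,4.588162e-01,0.000000e+00
24.825808,1.609347e+01,1.704291e-01,4.015933e-01,0.000000e+00
26.340000,1.349403e+01,1.695641e-01,3.644472e-01,0.000000e+00
26.965203,1.258263e+01,1.692104e-01,3.505725e-01,0.000000e+00
29.288964,9.828986e+00,1.679128e-01,3.052901e-01,0.000000e+00
30.970000,8.315434e+00,1.669908e-01,2.777153e-01,0.000000e+00
31.812977,7.671497e+00,1.665335e-01,2.652532e-01,0.000000e+00
34.554501,5.982801e+00,1.650695e-01,2.299703e-01,0.000000e+00
37.532278,4.662314e+00,1.635184e-01,1.989693e-01,0.000000e+00
40.766670,3.630702e+00,1.618777e-01,1.718071e-01,0.000000e+00
44.279789,2.825479e+00,1.601457e-01,1.480735e-01,0.000000e+00
48.095656,2.197491e+00,1.583209e-01,1.273910e-01,0.000000e+00
52.240360,1.708116e+00,1.564023e-01,1.094147e-01,0.000000e+00
53.160000,1.619537e+00,1.559852e-01,1.059355e-01,0.000000e+00
56.742239,1.327044e+00,1.543895e-01,9.382991e-02,0.000000e+00
59.540000,1.145409e+00,1.531743e-01,8.574319e-02,0.000000e+00
61.632073,1.030515e+00,1.522828e-01,8.035124e-02,0.000000e+00
66.943295,7.999249e-01,1.500829e-01,6.872063e-02,0.000000e+00
72.712218,6.207197e-01,1.477915e-01,5.870596e-02,0.000000e+00
78.978285,4.815265e-01,1.454109e-01,5.009950e-02,0.000000e+00
80.190000,4.595126e-01,1.449629e-01,4.865281e-02,0.000000e+00
80.997000,4.455849e-01,1.446666e-01,4.772346e-02,0.000000e+00
85.784339,3.734662e-01,1.429440e-01,4.271632e-02,0.000000e+00
93.176913,2.896134e-01,1.403947e-01,3.639264e-02,0.000000e+00
101.206551,2.245707e-01,1.377676e-01,3.098418e-02,0.000000e+00
109.928154,1.741354e-01,1.350678e-01,2.636436e-02,0.000000e+00
119.401351,1.350378e-01,1.323013e-01,2.242268e-02,0.000000e+00
121.780000,1.270903e-01,1.316320e-01,2.157143e-02,0.000000e+00
129.690913,1.047354e-01,1.294746e-01,1.906302e-02,0.000000e+00
140.510000,8.188858e-02,1.266838e-01,1.628324e-02,0.000000e+00
140.867192,8.125293e-02,1.265946e-01,1.620206e-02,0.000000e+00
153.006600,6.305681e-02,1.236688e-01,1.376785e-02,0.000000e+00
160.610000,5.435234e-02,1.219339e-01,1.251308e-02,0.000000e+00
166.192137,4.895688e-02,1.207047e-01,1.169837e-02,0.000000e+00
180.513955,3.803012e-02,1.177103e-01,9.940352e-03,0.000000e+00
196.069973,2.956102e-02,1.146935e-01,8.448105e-03,0.000000e+00
212.966551,2.299515e-02,1.116619e-01,7.182547e-03,0.000000e+00
223.200000,1.994649e-02,1.099370e-01,6.551978e-03,0.000000e+00
231.319213,1.790308e-02,1.086231e-01,6.110304e-03,0.000000e+00
244.700000,1.510831e-02,1.065555e-01,5.476656e-03,0.000000e+00
251.253438,1.395229e-02,1.055845e-01,5.202925e-03,0.000000e+00
272.905521,1.088536e-02,1.025528e-01,4.436196e-03,0.000000e+00
276.400000,1.047843e-02,1.020872e-01,4.329317e-03,0.000000e+00
284.300000,9.631487e-03,1.010571e-01,4.102360e-03,0.000000e+00
296.423499,8.503064e-03,9.953435e-02,3.789546e-03,0.000000e+00
302.850000,7.976963e-03,9.875407e-02,3.639169e-03,0.000000e+00
321.968169,6.651209e-03,9.653502e-02,3.245516e-03,0.000000e+00
344.280000,5.456460e-03,9.412154e-02,2.869604e-03,0.000000e+00
349.714183,5.210475e-03,9.356000e-02,2.789306e-03,0.000000e+00
356.010000,4.944062e-03,9.292150e-02,2.701103e-03,0.000000e+00
364.490000,4.613852e-03,9.208125e-02,2.589898e-03,0.000000e+00
379.851245,4.088521e-03,9.061390e-02,2.408364e-03,0.000000e+00
383.850000,3.965327e-03,9.024296e-02,2.364919e-03,0.000000e+00
411.100000,3.247682e-03,8.782713e-02,2.104615e-03,0.000000e+00
412.585406,3.213878e-03,8.770076e-02,2.092032e-03,0.000000e+00
443.900000,2.601431e-03,8.515296e-02,1.858652e-03,0.000000e+00
448.140475,2.531222e-03,8.482405e-02,1.831221e-03,0.000000e+00
486.759547,1.997712e-03,8.198671e-02,1.618122e-03,0.000000e+00
487.020000,1.994668e-03,8.196848e-02,1.616883e-03,0.000000e+00
511.000000,1.739977e-03,8.033797e-02,1.512341e-03,0.000000e+00
528.706666,1.580163e-03,7.919121e-02,1.445952e-03,0.000000e+00
574.268631,1.252861e-03,7.643962e-02,1.308732e-03,0.000000e+00
623.756956,9.958655e-04,7.373365e-02,1.201119e-03,0.000000e+00
636.990000,9.398591e-04,7.305388e-02,1.177915e-03,0.000000e+00
661.660000,8.467529e-04,7.183129e-02,1.139735e-03,0.000000e+00
677.510000,7.937062e-04,7.107473e-02,1.118280e-03,0.000000e+00
722.900000,6.655981e-04,6.902264e-02,1.067773e-03,0.000000e+00
735.895281,6.343716e-04,6.846409e-02,1.055831e-03,0.000000e+00
778.900000,5.447836e-04,6.669894e-02,1.022670e-03,0.000000e+00
799.311987,5.085279e-04,6.590276e-02,1.009815e-03,0.000000e+00
815.770000,4.817737e-04,6.527893e-02,1.000581e-03,0.000000e+00
867.380000,4.099202e-04,6.341987e-02,9.770379e-04,0.000000e+00
868.193708,4.089150e-04,6.339167e-02,9.767233e-04,0.000000e+00
943.011398,3.298802e-04,6.093169e-02,9.535208e-04,0.000000e+00
964.060000,3.116676e-04,6.028350e-02,9.486610e-04,0.000000e+00
1024.276598,2.670172e-04,5.852362e-02,9.376653e-04,4.742444e-06
1085.870000,2.304548e-04,5.685423e-02,9.297583e-04,1.329311e-04
1112.070000,2.171177e-04,5.618027e-02,9.271485e-04,1.874588e-04
1112.544928,2.168866e-04,5.616824e-02,9.271046e-04,1.884472e-04
1173.230000,1.901214e-04,5.468309e-02,9.223547e-04,3.147455e-04
1208.419894,1.768008e-04,5.386632e-02,9.202443e-04,3.879830e-04
1212.950000,1.751881e-04,5.376340e-02,9.200007e-04,3.974110e-04
1299.140000,1.482791e-04,5.189503e-02,9.163297e-04,5.767904e-04
1312.557006,1.446559e-04,5.161863e-02,9.158936e-04,6.047139e-04
1332.490000,1.395153e-04,5.121470e-02,9.152991e-04,6.461987e-04
1368.630000,1.308747e-04,5.050205e-02,9.143645e-04,7.214135e-04
1408.010000,1.223523e-04,4.975296e-02,9.135231e-04,8.033715e-04
1425.668265,1.188026e-04,4.942591e-02,9.131964e-04,8.401220e-04
1548.527030,9.794580e-05,4.728890e-02,9.115593e-04,1.095817e-03
1596.210000,9.133776e-05,4.651897e-02,9.111410e-04,1.195055e-03
1681.973304,8.106661e-05,4.520829e-02,9.105848e-04,1.373546e-03
1826.919480,6.736197e-05,4.318474e-02,9.100149e-04,1.675209e-03
1984.356575,5.619765e-05,4.121883e-02,9.096870e-04,2.002869e-03
2155.361011,4.707168e-05,3.931109e-02,9.095009e-04,2.358764e-03
2341.101971,3.958591e-05,3.746193e-02,9.093967e-04,2.745330e-03
2521.400000,3.400217e-05,3.585241e-02,9.093434e-04,3.120568e-03
2542.849393,3.342379e-05,3.567167e-02,9.093390e-04,3.165208e-03
2754.010000,2.849534e-05,3.400003e-02,9.093081e-04,3.604678e-03
2761.982653,2.833304e-05,3.394049e-02,9.093073e-04,3.621270e-03
3000.000000,2.411214e-05,3.226847e-02,9.092901e-04,4.116634e-03
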
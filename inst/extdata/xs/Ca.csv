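# element=Ca Z=20 A=40.0780 k_edge_keV=4.0381 l3_edge_keV=0.3462
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,1.178134e+02,1.924731e-01,1.024383e+00,0.000000e+00
10.861763,9.239144e+01,1.918651e-01,9.386350e-01,0.000000e+00
11.797789,7.237431e+01,1.912105e-01,8.539400e-01,0.000000e+00
12.814478,5.663289e+01,1.905060e-01,7.716085e-01,0.000000e+00
13.918782,4.426904e+01,1.897486e-01,6.928032e-01,0.000000e+00
15.118251,3.456956e+01,1.889349e-01,6.184667e-01,0.000000e+00
16.421085,2.696903e+01,1.880615e-01,5.492780e-01,0.000000e+00
17.836193,2.101982e+01,1.871249e-01,4.856417e-01,0.000000e+00
19.373249,1.636817e+01,1.861215e-01,4.277079e-01,0.000000e+00
21.042763,1.273484e+01,1.850478e-01,3.754144e-01,0.000000e+00
22.856150,9.899756e+00,1.839000e-01,3.285400e-01,0.000000e+00
24.825808,7.689678e+00,1.826748e-01,2.867583e-01,0.000000e+00
26.340000,6.413911e+00,1.817476e-01,2.597507e-01,0.000000e+00
26.965203,5.968434e+00,1.813685e-01,2.496847e-01,0.000000e+00
29.288964,4.629106e+00,1.799777e-01,2.169124e-01,0.000000e+00
30.970000,3.897787e+00,1.789894e-01,1.970145e-01,0.000000e+00
31.812977,3.587856e+00,1.784993e-01,1.880366e-01,0.000000e+00
34.554501,2.779017e+00,1.769301e-01,1.626694e-01,0.000000e+00
37.532278,2.151212e+00,1.752675e-01,1.404470e-01,0.000000e+00
40.766670,1.664293e+00,1.735090e-01,1.210326e-01,0.000000e+00
44.279789,1.286914e+00,1.716525e-01,1.041168e-01,0.000000e+00
48.095656,9.946332e-01,1.696966e-01,8.941635e-02,0.000000e+00
52.240360,7.684058e-01,1.676402e-01,7.667353e-02,0.000000e+00
53.160000,7.276284e-01,1.671931e-01,7.421121e-02,0.000000e+00
56.742239,5.934094e-01,1.654828e-01,6.565426e-02,0.000000e+00
59.540000,5.104348e-01,1.641802e-01,5.994762e-02,0.000000e+00
61.632073,4.581178e-01,1.632246e-01,5.614706e-02,0.000000e+00
66.943295,3.535760e-01,1.608667e-01,4.796173e-02,0.000000e+00
72.712218,2.728328e-01,1.584107e-01,4.092813e-02,0.000000e+00
78.978285,2.104964e-01,1.558589e-01,3.489484e-02,0.000000e+00
80.190000,2.006736e-01,1.553788e-01,3.388175e-02,0.000000e+00
80.997000,1.944646e-01,1.550613e-01,3.323110e-02,0.000000e+00
85.784339,1.623884e-01,1.532148e-01,2.972780e-02,0.000000e+00
93.176913,1.252727e-01,1.504824e-01,2.530892e-02,0.000000e+00
101.206551,9.664504e-02,1.476665e-01,2.153464e-02,0.000000e+00
109.928154,7.456872e-02,1.447727e-01,1.831459e-02,0.000000e+00
119.401351,5.754684e-02,1.418074e-01,1.557015e-02,0.000000e+00
121.780000,5.409842e-02,1.410900e-01,1.497784e-02,0.000000e+00
129.690913,4.442315e-02,1.387776e-01,1.323322e-02,0.000000e+00
140.510000,3.457820e-02,1.357863e-01,1.130135e-02,0.000000e+00
140.867192,3.430501e-02,1.356907e-01,1.124496e-02,0.000000e+00
153.006600,2.650361e-02,1.325546e-01,9.554695e-03,0.000000e+00
160.610000,2.278630e-02,1.306951e-01,8.683986e-03,0.000000e+00
166.192137,2.048768e-02,1.293776e-01,8.118876e-03,0.000000e+00
180.513955,1.584760e-02,1.261681e-01,6.900180e-03,0.000000e+00
196.069973,1.226767e-02,1.229344e-01,5.866674e-03,0.000000e+00
212.966551,9.504638e-03,1.196850e-01,4.991090e-03,0.000000e+00
223.200000,8.226173e-03,1.178362e-01,4.555251e-03,0.000000e+00
231.319213,7.371103e-03,1.164279e-01,4.250190e-03,0.000000e+00
244.700000,6.204337e-03,1.142118e-01,3.812920e-03,0.000000e+00
251.253438,5.722736e-03,1.131709e-01,3.624195e-03,0.000000e+00
272.905521,4.448381e-03,1.099214e-01,3.096305e-03,0.000000e+00
276.400000,4.279700e-03,1.094223e-01,3.022826e-03,0.000000e+00
284.300000,3.928968e-03,1.083183e-01,2.866900e-03,0.000000e+00
296.423499,3.462439e-03,1.066861e-01,2.652263e-03,0.000000e+00
302.850000,3.245255e-03,1.058498e-01,2.549217e-03,0.000000e+00
321.968169,2.698985e-03,1.034713e-01,2.279980e-03,0.000000e+00
344.280000,2.208120e-03,1.008844e-01,2.023784e-03,0.000000e+00
349.714183,2.107247e-03,1.002825e-01,1.969207e-03,0.000000e+00
356.010000,1.998078e-03,9.959812e-02,1.909329e-03,0.000000e+00
364.490000,1.862888e-03,9.869749e-02,1.833953e-03,0.000000e+00
379.851245,1.648112e-03,9.712471e-02,1.711237e-03,0.000000e+00
383.850000,1.597802e-03,9.672711e-02,1.681937e-03,0.000000e+00
411.100000,1.305206e-03,9.413770e-02,1.507064e-03,0.000000e+00
412.585406,1.291444e-03,9.400226e-02,1.498645e-03,0.000000e+00
443.900000,1.042504e-03,9.127139e-02,1.343211e-03,0.000000e+00
448.140475,1.014016e-03,9.091884e-02,1.325046e-03,0.000000e+00
486.759547,7.979156e-04,8.787763e-02,1.184890e-03,0.000000e+00
487.020000,7.966849e-04,8.785810e-02,1.184081e-03,0.000000e+00
511.000000,6.937900e-04,8.611043e-02,1.116107e-03,0.000000e+00
528.706666,6.293272e-04,8.488127e-02,1.073283e-03,0.000000e+00
574.268631,4.975853e-04,8.193197e-02,9.858447e-04,0.000000e+00
623.756956,3.944521e-04,7.903157e-02,9.186137e-04,0.000000e+00
636.990000,3.720190e-04,7.830296e-02,9.043194e-04,0.000000e+00
661.660000,3.347634e-04,7.699252e-02,8.809891e-04,0.000000e+00
677.510000,3.135598e-04,7.618161e-02,8.679949e-04,0.000000e+00
722.900000,2.624278e-04,7.398207e-02,8.377956e-04,0.000000e+00
735.895281,2.499818e-04,7.338338e-02,8.307477e-04,0.000000e+00
778.900000,2.143170e-04,7.149140e-02,8.113999e-04,0.000000e+00
799.311987,1.999031e-04,7.063801e-02,8.040007e-04,0.000000e+00
815.770000,1.892745e-04,6.996937e-02,7.987255e-04,0.000000e+00
867.380000,1.607648e-04,6.797673e-02,7.854501e-04,0.000000e+00
868.193708,1.603664e-04,6.794650e-02,7.852745e-04,0.000000e+00
943.011398,1.290762e-04,6.530977e-02,7.724971e-04,0.000000e+00
964.060000,1.218773e-04,6.461501e-02,7.698688e-04,0.000000e+00
1024.276598,1.042491e-04,6.272867e-02,7.639991e-04,3.910153e-06
1085.870000,8.983849e-05,6.093933e-02,7.598579e-04,1.096019e-04
1112.070000,8.458799e-05,6.021694e-02,7.585091e-04,1.545601e-04
1112.544928,8.449704e-05,6.020405e-02,7.584865e-04,1.553750e-04
1173.230000,7.397120e-05,5.861219e-02,7.560600e-04,2.595082e-04
1208.419894,6.873855e-05,5.773673e-02,7.549953e-04,3.198926e-04
1212.950000,6.810532e-05,5.762642e-02,7.548730e-04,3.276661e-04
1299.140000,5.754922e-05,5.562380e-02,7.530480e-04,4.755646e-04
1312.557006,5.612939e-05,5.532754e-02,7.528337e-04,4.985877e-04
1332.490000,5.411555e-05,5.489459e-02,7.525425e-04,5.327919e-04
1368.630000,5.073236e-05,5.413074e-02,7.520873e-04,5.948067e-04
1408.010000,4.739778e-05,5.332782e-02,7.516804e-04,6.623811e-04
1425.668265,4.600956e-05,5.297727e-02,7.515232e-04,6.926820e-04
1548.527030,3.786213e-05,5.068671e-02,7.507440e-04,9.035027e-04
1596.210000,3.528434e-05,4.986146e-02,7.505476e-04,9.853247e-04
1681.973304,3.128141e-05,4.845660e-02,7.502887e-04,1.132491e-03
1826.919480,2.594847e-05,4.628766e-02,7.500270e-04,1.381213e-03
1984.356575,2.161196e-05,4.418050e-02,7.498786e-04,1.651369e-03
2155.361011,1.807343e-05,4.213568e-02,7.497955e-04,1.944805e-03
2341.101971,1.517579e-05,4.015366e-02,7.497495e-04,2.263529e-03
2521.400000,1.301776e-05,3.842849e-02,7.497263e-04,2.572913e-03
2542.849393,1.279441e-05,3.823476e-02,7.497243e-04,2.609720e-03
2754.010000,1.089274e-05,3.644301e-02,7.497110e-04,2.972063e-03
2761.982653,1.083017e-05,3.637919e-02,7.497106e-04,2.985743e-03
3000.000000,9.204021e-06,3.458703e-02,7.497032e-04,3.394172e-03
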
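# element=C Z=6 A=12.0110 k_edge_keV=0.2838 l3_edge_keV=NA
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,2.076112e+00,1.926718e-01,1.888785e-01,0.000000e+00
10.861763,1.583205e+00,1.920632e-01,1.678667e-01,0.000000e+00
11.797789,1.206727e+00,1.914079e-01,1.485097e-01,0.000000e+00
12.814478,9.193417e-01,1.907027e-01,1.308630e-01,0.000000e+00
13.918782,7.000868e-01,1.899445e-01,1.149161e-01,0.000000e+00
15.118251,5.328988e-01,1.891300e-01,1.006087e-01,0.000000e+00
16.421085,4.054775e-01,1.882557e-01,8.784623e-02,0.000000e+00
17.836193,3.084105e-01,1.873181e-01,7.651505e-02,0.000000e+00
19.373249,2.345005e-01,1.863137e-01,6.649341e-02,0.000000e+00
21.042763,1.782471e-01,1.852388e-01,5.765933e-02,0.000000e+00
22.856150,1.354496e-01,1.840899e-01,4.989540e-02,0.000000e+00
24.825808,1.029016e-01,1.828634e-01,4.309125e-02,0.000000e+00
26.340000,8.450395e-02,1.819353e-01,3.875060e-02,0.000000e+00
26.965203,7.815719e-02,1.815557e-01,3.714453e-02,0.000000e+00
29.288964,5.935146e-02,1.801635e-01,3.196112e-02,0.000000e+00
30.970000,4.928196e-02,1.791742e-01,2.884955e-02,0.000000e+00
31.812977,4.506337e-02,1.786836e-01,2.745489e-02,0.000000e+00
34.554501,3.421056e-02,1.771128e-01,2.354733e-02,0.000000e+00
37.532278,2.596906e-02,1.754485e-01,2.016714e-02,0.000000e+00
40.766670,1.971185e-02,1.736881e-01,1.724984e-02,0.000000e+00
44.279789,1.496202e-02,1.718297e-01,1.473742e-02,0.000000e+00
48.095656,1.135695e-02,1.698718e-01,1.257793e-02,0.000000e+00
52.240360,8.621049e-03,1.678132e-01,1.072510e-02,0.000000e+00
53.160000,8.133837e-03,1.673657e-01,1.036921e-02,0.000000e+00
56.742239,6.544917e-03,1.656536e-01,9.137956e-03,0.000000e+00
59.540000,5.575262e-03,1.643497e-01,8.321725e-03,0.000000e+00
61.632073,4.969511e-03,1.633932e-01,7.780351e-03,0.000000e+00
66.943295,3.774065e-03,1.610328e-01,6.620586e-03,0.000000e+00
72.712218,2.866905e-03,1.585742e-01,5.630969e-03,0.000000e+00
78.978285,2.178454e-03,1.560198e-01,4.787404e-03,0.000000e+00
80.190000,2.071082e-03,1.555392e-01,4.646249e-03,0.000000e+00
80.997000,2.003383e-03,1.552213e-01,4.555671e-03,0.000000e+00
85.784339,1.655920e-03,1.533730e-01,4.069004e-03,0.000000e+00
93.176913,1.259248e-03,1.506377e-01,3.457716e-03,0.000000e+00
101.206551,9.580575e-04,1.478189e-01,2.937987e-03,0.000000e+00
109.928154,7.293042e-04,1.449222e-01,2.496447e-03,0.000000e+00
119.401351,5.555112e-04,1.419538e-01,2.121631e-03,0.000000e+00
121.780000,5.206267e-04,1.412357e-01,2.040938e-03,0.000000e+00
129.690913,4.234242e-04,1.389209e-01,1.803729e-03,0.000000e+00
140.510000,3.256844e-04,1.359265e-01,1.541985e-03,0.000000e+00
140.867192,3.229913e-04,1.358308e-01,1.534361e-03,0.000000e+00
153.006600,2.465889e-04,1.326915e-01,1.306385e-03,0.000000e+00
160.610000,2.105663e-04,1.308301e-01,1.189418e-03,0.000000e+00
166.192137,1.884346e-04,1.295112e-01,1.113718e-03,0.000000e+00
180.513955,1.441424e-04,1.262983e-01,9.511958e-04,0.000000e+00
196.069973,1.103844e-04,1.230614e-01,8.144316e-04,0.000000e+00
212.966551,8.463523e-05,1.198086e-01,6.997077e-04,0.000000e+00
223.200000,7.282966e-05,1.179578e-01,6.431597e-04,0.000000e+00
231.319213,6.497819e-05,1.165481e-01,6.038717e-04,0.000000e+00
244.700000,5.432928e-05,1.143297e-01,5.480876e-04,0.000000e+00
251.253438,4.995786e-05,1.132878e-01,5.242468e-04,0.000000e+00
272.905521,3.846883e-05,1.100349e-01,4.585517e-04,0.000000e+00
276.400000,3.695751e-05,1.095353e-01,4.495484e-04,0.000000e+00
284.300000,3.382294e-05,1.084301e-01,4.305826e-04,0.000000e+00
296.423499,2.967112e-05,1.067963e-01,4.048279e-04,0.000000e+00
302.850000,2.774576e-05,1.059590e-01,3.926303e-04,0.000000e+00
321.968169,2.292617e-05,1.035781e-01,3.613760e-04,0.000000e+00
344.280000,1.862742e-05,1.009885e-01,3.326597e-04,0.000000e+00
349.714183,1.774828e-05,1.003860e-01,3.267003e-04,0.000000e+00
356.010000,1.679862e-05,9.970094e-02,3.202352e-04,0.000000e+00
364.490000,1.562529e-05,9.879938e-02,3.122140e-04,0.000000e+00
379.851245,1.376780e-05,9.722498e-02,2.994652e-04,0.000000e+00
383.850000,1.333393e-05,9.682697e-02,2.964837e-04,0.000000e+00
411.100000,1.082093e-05,9.423489e-02,2.792657e-04,0.000000e+00
412.585406,1.070320e-05,9.409930e-02,2.784641e-04,0.000000e+00
443.900000,8.581673e-06,9.136561e-02,2.641973e-04,0.000000e+00
448.140475,8.339940e-06,9.101271e-02,2.626019e-04,0.000000e+00
486.759547,6.514360e-06,8.796836e-02,2.508898e-04,0.000000e+00
487.020000,6.504008e-06,8.794880e-02,2.508255e-04,0.000000e+00
511.000000,5.640433e-06,8.619933e-02,2.455826e-04,0.000000e+00
528.706666,5.101535e-06,8.496890e-02,2.424489e-04,0.000000e+00
574.268631,4.006000e-06,8.201656e-02,2.365173e-04,0.000000e+00
623.756956,3.154736e-06,7.911316e-02,2.324548e-04,0.000000e+00
636.990000,2.970436e-06,7.838380e-02,2.316561e-04,0.000000e+00
661.660000,2.665129e-06,7.707201e-02,2.304072e-04,0.000000e+00
677.510000,2.491824e-06,7.626026e-02,2.297430e-04,0.000000e+00
722.900000,2.075403e-06,7.405845e-02,2.282947e-04,0.000000e+00
735.895281,1.974392e-06,7.345914e-02,2.279775e-04,0.000000e+00
778.900000,1.685784e-06,7.156521e-02,2.271522e-04,0.000000e+00
799.311987,1.569528e-06,7.071094e-02,2.268556e-04,0.000000e+00
815.770000,1.483956e-06,7.004161e-02,2.266512e-04,0.000000e+00
867.380000,1.255123e-06,6.804691e-02,2.261649e-04,0.000000e+00
868.193708,1.251933e-06,6.801665e-02,2.261588e-04,0.000000e+00
943.011398,1.002127e-06,6.537719e-02,2.257351e-04,0.000000e+00
964.060000,9.448776e-07,6.468171e-02,2.256541e-04,0.000000e+00
1024.276598,8.050909e-07,6.279343e-02,2.254824e-04,1.174257e-06
1085.870000,6.912880e-07,6.100224e-02,2.253699e-04,3.291453e-05
1112.070000,6.499406e-07,6.027911e-02,2.253351e-04,4.641589e-05
1112.544928,6.492250e-07,6.026620e-02,2.253345e-04,4.666063e-05
1173.230000,5.665445e-07,5.867270e-02,2.252744e-04,7.793282e-05
1208.419894,5.255535e-07,5.779634e-02,2.252492e-04,9.606686e-05
1212.950000,5.205983e-07,5.768591e-02,2.252464e-04,9.840131e-05
1299.140000,4.381771e-07,5.568122e-02,2.252054e-04,1.428167e-04
1312.557006,4.271191e-07,5.538466e-02,2.252008e-04,1.497307e-04
1332.490000,4.114469e-07,5.495127e-02,2.251946e-04,1.600026e-04
1368.630000,3.851515e-07,5.418662e-02,2.251851e-04,1.786262e-04
1408.010000,3.592769e-07,5.338288e-02,2.251768e-04,1.989195e-04
1425.668265,3.485182e-07,5.303196e-02,2.251737e-04,2.080191e-04
1548.527030,2.855452e-07,5.073904e-02,2.251586e-04,2.713306e-04
1596.210000,2.656869e-07,4.991294e-02,2.251550e-04,2.959026e-04
1681.973304,2.349201e-07,4.850663e-02,2.251503e-04,3.400981e-04
1826.919480,1.940789e-07,4.633544e-02,2.251458e-04,4.147916e-04
1984.356575,1.610127e-07,4.422611e-02,2.251434e-04,4.959220e-04
2155.361011,1.341437e-07,4.217918e-02,2.251421e-04,5.840439e-04
2341.101971,1.122294e-07,4.019511e-02,2.251414e-04,6.797598e-04
2521.400000,9.596868e-08,3.846816e-02,2.251411e-04,7.726709e-04
2542.849393,9.428898e-08,3.827423e-02,2.251410e-04,7.837242e-04
2754.010000,8.001491e-08,3.648064e-02,2.251408e-04,8.925393e-04
2761.982653,7.954610e-08,3.641675e-02,2.251408e-04,8.966478e-04
3000.000000,6.738451e-08,3.462274e-02,2.251407e-04,1.019303e-03
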
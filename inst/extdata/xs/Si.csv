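# element=Si Z=14 A=28.0850 k_edge_keV=1.8389 l3_edge_keV=0.0996
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,4.047313e+01,1.922648e-01,6.302321e-01,0.000000e+00
10.861763,3.139474e+01,1.916574e-01,5.716260e-01,0.000000e+00
11.797789,2.433179e+01,1.910035e-01,5.150450e-01,0.000000e+00
12.814478,1.884210e+01,1.902998e-01,4.612398e-01,0.000000e+00
13.918782,1.457921e+01,1.895432e-01,4.107911e-01,0.000000e+00
15.118251,1.127196e+01,1.887304e-01,3.640891e-01,0.000000e+00
16.421085,8.708394e+00,1.878579e-01,3.213361e-01,0.000000e+00
17.836193,6.722975e+00,1.869223e-01,2.825676e-01,0.000000e+00
19.373249,5.186598e+00,1.859200e-01,2.476867e-01,0.000000e+00
21.042763,3.998656e+00,1.848475e-01,2.165020e-01,0.000000e+00
22.856150,3.080841e+00,1.837010e-01,1.887638e-01,0.000000e+00
24.825808,2.372259e+00,1.824771e-01,1.641937e-01,0.000000e+00
26.340000,1.966588e+00,1.815509e-01,1.483843e-01,0.000000e+00
26.965203,1.825606e+00,1.811722e-01,1.425063e-01,0.000000e+00
29.288964,1.404168e+00,1.797829e-01,1.234228e-01,0.000000e+00
30.970000,1.175815e+00,1.787957e-01,1.118775e-01,0.000000e+00
31.812977,1.079477e+00,1.783061e-01,1.066789e-01,0.000000e+00
34.554501,8.294810e-01,1.767386e-01,9.202846e-02,0.000000e+00
37.532278,6.371108e-01,1.750778e-01,7.924430e-02,0.000000e+00
40.766670,4.891663e-01,1.733212e-01,6.811824e-02,0.000000e+00
44.279789,3.754478e-01,1.714667e-01,5.846019e-02,0.000000e+00
48.095656,2.880802e-01,1.695129e-01,5.009725e-02,0.000000e+00
52.240360,2.209876e-01,1.674587e-01,4.287279e-02,0.000000e+00
53.160000,2.089527e-01,1.670122e-01,4.147961e-02,0.000000e+00
56.742239,1.694863e-01,1.653036e-01,3.664556e-02,0.000000e+00
59.540000,1.452144e-01,1.640025e-01,3.342838e-02,0.000000e+00
61.632073,1.299676e-01,1.630480e-01,3.128883e-02,0.000000e+00
66.943295,9.965353e-02,1.606926e-01,2.668948e-02,0.000000e+00
72.712218,7.640678e-02,1.582392e-01,2.274707e-02,0.000000e+00
78.978285,5.858388e-02,1.556902e-01,1.937287e-02,0.000000e+00
80.190000,5.578712e-02,1.552106e-01,1.880698e-02,0.000000e+00
80.997000,5.402109e-02,1.548934e-01,1.844366e-02,0.000000e+00
85.784339,4.492192e-02,1.530490e-01,1.648889e-02,0.000000e+00
93.176913,3.445090e-02,1.503195e-01,1.402687e-02,0.000000e+00
101.206551,2.642619e-02,1.475066e-01,1.192734e-02,0.000000e+00
109.928154,2.027643e-02,1.446160e-01,1.013865e-02,0.000000e+00
119.401351,1.556339e-02,1.416539e-01,8.616131e-03,0.000000e+00
121.780000,1.461221e-02,1.409373e-01,8.287784e-03,0.000000e+00
129.690913,1.195107e-02,1.386274e-01,7.321226e-03,0.000000e+00
140.510000,9.256520e-03,1.356393e-01,6.251966e-03,0.000000e+00
140.867192,9.181965e-03,1.355438e-01,6.220773e-03,0.000000e+00
153.006600,7.058764e-03,1.324112e-01,5.286302e-03,0.000000e+00
160.610000,6.051502e-03,1.305537e-01,4.805376e-03,0.000000e+00
166.192137,5.430322e-03,1.292376e-01,4.493435e-03,0.000000e+00
180.513955,4.180885e-03,1.260315e-01,3.821330e-03,0.000000e+00
196.069973,3.221811e-03,1.228014e-01,3.252208e-03,0.000000e+00
212.966551,2.485231e-03,1.195555e-01,2.770924e-03,0.000000e+00
223.200000,2.145718e-03,1.177086e-01,2.531774e-03,0.000000e+00
231.319213,1.919181e-03,1.163019e-01,2.364601e-03,0.000000e+00
244.700000,1.610849e-03,1.140882e-01,2.125376e-03,0.000000e+00
251.253438,1.483874e-03,1.130484e-01,2.022305e-03,0.000000e+00
272.905521,1.148846e-03,1.098024e-01,1.734762e-03,0.000000e+00
276.400000,1.104616e-03,1.093039e-01,1.694848e-03,0.000000e+00
284.300000,1.012747e-03,1.082011e-01,1.610260e-03,0.000000e+00
296.423499,8.907664e-04,1.065706e-01,1.494109e-03,0.000000e+00
302.850000,8.340729e-04,1.057352e-01,1.438485e-03,0.000000e+00
321.968169,6.917640e-04,1.033593e-01,1.293678e-03,0.000000e+00
344.280000,5.642899e-04,1.007752e-01,1.156803e-03,0.000000e+00
349.714183,5.381475e-04,1.001739e-01,1.127793e-03,0.000000e+00
356.010000,5.098775e-04,9.949031e-02,1.096037e-03,0.000000e+00
364.490000,4.749034e-04,9.859065e-02,1.056177e-03,0.000000e+00
379.851245,4.194233e-04,9.701958e-02,9.916009e-04,0.000000e+00
383.850000,4.064432e-04,9.662241e-02,9.762482e-04,0.000000e+00
411.100000,3.310837e-04,9.403581e-02,8.852589e-04,0.000000e+00
412.585406,3.275454e-04,9.390051e-02,8.809099e-04,0.000000e+00
443.900000,2.636414e-04,9.117259e-02,8.012696e-04,0.000000e+00
448.140475,2.563418e-04,9.082043e-02,7.920540e-04,0.000000e+00
486.759547,2.010751e-04,8.778251e-02,7.217787e-04,0.000000e+00
487.020000,2.007609e-04,8.776300e-02,7.213779e-04,0.000000e+00
511.000000,1.745194e-04,8.601723e-02,6.879451e-04,0.000000e+00
528.706666,1.581069e-04,8.478939e-02,6.671561e-04,0.000000e+00
574.268631,1.246408e-04,8.184329e-02,6.255311e-04,0.000000e+00
623.756956,9.852556e-05,7.894603e-02,5.944980e-04,0.000000e+00
636.990000,9.285646e-05,7.821821e-02,5.880399e-04,0.000000e+00
661.660000,8.345171e-05,7.690919e-02,5.776264e-04,0.000000e+00
677.510000,7.810515e-05,7.609915e-02,5.719023e-04,0.000000e+00
722.900000,6.523199e-05,7.390199e-02,5.588450e-04,0.000000e+00
735.895281,6.210319e-05,7.330395e-02,5.558544e-04,0.000000e+00
778.900000,5.314873e-05,7.141402e-02,5.477762e-04,0.000000e+00
799.311987,4.953494e-05,7.056155e-02,5.447448e-04,0.000000e+00
815.770000,4.687223e-05,6.989363e-02,5.426060e-04,0.000000e+00
867.380000,3.973933e-05,6.790315e-02,5.373181e-04,0.000000e+00
868.193708,3.963975e-05,6.787296e-02,5.372492e-04,0.000000e+00
943.011398,3.182933e-05,6.523907e-02,5.323189e-04,0.000000e+00
964.060000,3.003541e-05,6.454507e-02,5.313287e-04,0.000000e+00
1024.276598,2.564802e-05,6.266077e-02,5.291545e-04,2.734144e-06
1085.870000,2.206783e-05,6.087337e-02,5.276578e-04,7.663831e-05
1112.070000,2.076497e-05,6.015176e-02,5.271785e-04,1.080749e-04
1112.544928,2.074241e-05,6.013888e-02,5.271705e-04,1.086448e-04
1173.230000,1.813341e-05,5.854875e-02,5.263207e-04,1.814591e-04
1208.419894,1.683793e-05,5.767424e-02,5.259537e-04,2.236824e-04
1212.950000,1.668123e-05,5.756404e-02,5.259118e-04,2.291180e-04
1299.140000,1.407154e-05,5.556359e-02,5.252939e-04,3.325349e-04
1312.557006,1.372091e-05,5.526765e-02,5.252223e-04,3.486336e-04
1332.490000,1.322376e-05,5.483517e-02,5.251256e-04,3.725506e-04
1368.630000,1.238901e-05,5.407214e-02,5.249753e-04,4.159140e-04
1408.010000,1.156686e-05,5.327010e-02,5.248421e-04,4.631649e-04
1425.668265,1.122477e-05,5.291993e-02,5.247909e-04,4.843526e-04
1548.527030,9.219391e-06,5.063184e-02,5.245407e-04,6.317673e-04
1596.210000,8.585819e-06,4.980749e-02,5.244787e-04,6.889807e-04
1681.973304,7.602948e-06,4.840415e-02,5.243977e-04,7.918857e-04
1826.919480,6.295573e-06,4.623755e-02,5.243171e-04,9.658025e-04
1984.356575,5.234486e-06,4.413268e-02,5.242723e-04,1.154707e-03
2155.361011,4.370229e-06,4.209007e-02,5.242475e-04,1.359890e-03
2341.101971,3.663745e-06,4.011019e-02,5.242340e-04,1.582755e-03
2521.400000,3.138435e-06,3.838689e-02,5.242273e-04,1.799090e-03
2542.849393,3.084113e-06,3.819337e-02,5.242267e-04,1.824826e-03
2754.010000,2.621984e-06,3.640357e-02,5.242229e-04,2.078192e-03
2761.982653,2.606790e-06,3.633981e-02,5.242228e-04,2.087758e-03
3000.000000,2.212246e-06,3.454959e-02,5.242207e-04,2.373348e-03
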
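# element=Pb Z=82 A=207.2000 k_edge_keV=88.0045 l3_edge_keV=13.0352
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,3.074257e-17,1.526406e-01,4.782566e+00,0.000000e+00
10.861763,2.409532e-17,1.521585e-01,4.558780e+00,0.000000e+00
11.797789,1.886294e-17,1.516393e-01,4.318477e+00,0.000000e+00
12.814478,1.474985e-17,1.510807e-01,4.063703e+00,0.000000e+00
13.035200,1.401711e-17,1.509601e-01,4.009510e+00,0.000000e+00
13.035200,3.073517e+02,1.509601e-01,4.009510e+00,0.000000e+00
13.918782,2.581716e+02,1.504800e-01,3.797282e+00,0.000000e+00
15.118251,2.069152e+02,1.498347e-01,3.522742e+00,0.000000e+00
16.421085,1.655492e+02,1.491420e-01,3.244164e+00,0.000000e+00
17.836193,1.322262e+02,1.483993e-01,2.965944e+00,0.000000e+00
19.373249,1.054338e+02,1.476035e-01,2.692504e+00,0.000000e+00
21.042763,8.393384e+01,1.467520e-01,2.427986e+00,0.000000e+00
22.856150,6.671417e+01,1.458418e-01,2.175969e+00,0.000000e+00
24.825808,5.294845e+01,1.448701e-01,1.939264e+00,0.000000e+00
26.340000,4.483229e+01,1.441348e-01,1.780251e+00,0.000000e+00
26.965203,4.196372e+01,1.438341e-01,1.719799e+00,0.000000e+00
29.288964,3.321326e+01,1.427312e-01,1.518622e+00,0.000000e+00
30.970000,2.834196e+01,1.419474e-01,1.393302e+00,0.000000e+00
31.812977,2.625406e+01,1.415587e-01,1.335991e+00,0.000000e+00
34.554501,2.072806e+01,1.403143e-01,1.171523e+00,0.000000e+00
37.532278,1.634661e+01,1.389958e-01,1.024375e+00,0.000000e+00
40.766670,1.287752e+01,1.376012e-01,8.934109e-01,0.000000e+00
44.279789,1.013445e+01,1.361289e-01,7.773485e-01,0.000000e+00
48.095656,7.968205e+00,1.345778e-01,6.748598e-01,0.000000e+00
52.240360,6.259516e+00,1.329469e-01,5.846420e-01,0.000000e+00
53.160000,5.947941e+00,1.325924e-01,5.670468e-01,0.000000e+00
56.742239,4.913255e+00,1.312360e-01,5.054561e-01,0.000000e+00
59.540000,4.265642e+00,1.302030e-01,4.639710e-01,0.000000e+00
61.632073,3.853674e+00,1.294452e-01,4.361463e-01,0.000000e+00
66.943295,3.020554e+00,1.275752e-01,3.756449e-01,0.000000e+00
72.712218,2.366106e+00,1.256275e-01,3.229729e-01,0.000000e+00
78.978285,1.852457e+00,1.236038e-01,2.772358e-01,0.000000e+00
80.190000,1.770714e+00,1.232230e-01,2.695018e-01,0.000000e+00
80.997000,1.718917e+00,1.229712e-01,2.645264e-01,0.000000e+00
85.784339,1.449640e+00,1.215069e-01,2.376195e-01,0.000000e+00
88.004500,1.343720e+00,1.208444e-01,2.264955e-01,0.000000e+00
88.004500,8.172880e+00,1.208444e-01,2.264955e-01,0.000000e+00
93.176913,7.032370e+00,1.193399e-01,2.033863e-01,0.000000e+00
101.206551,5.653565e+00,1.171068e-01,1.738704e-01,0.000000e+00
109.928154,4.541483e+00,1.148119e-01,1.484742e-01,0.000000e+00
119.401351,3.645437e+00,1.124603e-01,1.266637e-01,0.000000e+00
121.780000,3.458826e+00,1.118913e-01,1.219356e-01,0.000000e+00
129.690913,2.924220e+00,1.100575e-01,1.079646e-01,0.000000e+00
140.510000,2.360324e+00,1.076852e-01,9.241292e-02,0.000000e+00
140.867192,2.344338e+00,1.076094e-01,9.195764e-02,0.000000e+00
153.006600,1.878570e+00,1.051224e-01,7.827398e-02,0.000000e+00
160.610000,1.649369e+00,1.036477e-01,7.119591e-02,0.000000e+00
166.192137,1.504815e+00,1.026028e-01,6.659071e-02,0.000000e+00
180.513955,1.205150e+00,1.000575e-01,5.662628e-02,0.000000e+00
196.069973,9.650680e-01,9.749306e-02,4.813613e-02,0.000000e+00
212.966551,7.728420e-01,9.491611e-02,4.090856e-02,0.000000e+00
223.200000,6.813180e-01,9.344990e-02,3.729628e-02,0.000000e+00
231.319213,6.190109e-01,9.233307e-02,3.476089e-02,0.000000e+00
244.700000,5.323507e-01,9.057558e-02,3.111472e-02,0.000000e+00
251.253438,4.959532e-01,8.975013e-02,2.953587e-02,0.000000e+00
272.905521,3.975382e-01,8.717309e-02,2.509850e-02,0.000000e+00
276.400000,3.842506e-01,8.677731e-02,2.447784e-02,0.000000e+00
284.300000,3.563987e-01,8.590175e-02,2.315781e-02,0.000000e+00
296.423499,3.188417e-01,8.460734e-02,2.133312e-02,0.000000e+00
302.850000,3.011391e-01,8.394408e-02,2.045342e-02,0.000000e+00
321.968169,2.559133e-01,8.205782e-02,1.814086e-02,0.000000e+00
344.280000,2.142793e-01,8.000628e-02,1.591548e-02,0.000000e+00
349.714183,2.055874e-01,7.952895e-02,1.543732e-02,0.000000e+00
356.010000,1.961224e-01,7.898621e-02,1.491072e-02,0.000000e+00
364.490000,1.843126e-01,7.827197e-02,1.424450e-02,0.000000e+00
379.851245,1.653301e-01,7.702468e-02,1.315062e-02,0.000000e+00
383.850000,1.608412e-01,7.670936e-02,1.288748e-02,0.000000e+00
411.100000,1.343756e-01,7.465583e-02,1.129719e-02,0.000000e+00
412.585406,1.331145e-01,7.454842e-02,1.121962e-02,0.000000e+00
443.900000,1.100047e-01,7.238270e-02,9.765559e-03,0.000000e+00
448.140475,1.073210e-01,7.210312e-02,9.592394e-03,0.000000e+00
486.759547,8.665579e-02,6.969129e-02,8.224900e-03,0.000000e+00
487.020000,8.653639e-02,6.967579e-02,8.216812e-03,0.000000e+00
511.000000,7.647516e-02,6.828981e-02,7.526883e-03,0.000000e+00
528.706666,7.008625e-02,6.731503e-02,7.079799e-03,0.000000e+00
574.268631,5.678832e-02,6.497609e-02,6.125417e-03,0.000000e+00
623.756956,4.610462e-02,6.267593e-02,5.334825e-03,0.000000e+00
636.990000,4.374238e-02,6.209811e-02,5.157297e-03,0.000000e+00
661.660000,3.978448e-02,6.105886e-02,4.857923e-03,0.000000e+00
677.510000,3.751086e-02,6.041577e-02,4.685007e-03,0.000000e+00
722.900000,3.195739e-02,5.867142e-02,4.260792e-03,0.000000e+00
735.895281,3.058888e-02,5.819663e-02,4.156115e-03,0.000000e+00
778.900000,2.662591e-02,5.669620e-02,3.853738e-03,0.000000e+00
799.311987,2.500515e-02,5.601942e-02,3.730821e-03,0.000000e+00
815.770000,2.380222e-02,5.548915e-02,3.640080e-03,0.000000e+00
867.380000,2.053957e-02,5.390889e-02,3.397154e-03,0.000000e+00
868.193708,2.049358e-02,5.388492e-02,3.393773e-03,0.000000e+00
943.011398,1.684185e-02,5.179386e-02,3.131178e-03,0.000000e+00
964.060000,1.598959e-02,5.124288e-02,3.072022e-03,0.000000e+00
1024.276598,1.388043e-02,4.974692e-02,2.930535e-03,1.271387e-05
1085.870000,1.212974e-02,4.832789e-02,2.819930e-03,3.563709e-04
1112.070000,1.148513e-02,4.775500e-02,2.781175e-03,5.025524e-04
1112.544928,1.147393e-02,4.774477e-02,2.780512e-03,5.052022e-04
1173.230000,1.016931e-02,4.648235e-02,2.706057e-03,8.437913e-04
1208.419894,9.514100e-03,4.578807e-02,2.670939e-03,1.040131e-03
1212.950000,9.434486e-03,4.570059e-02,2.666787e-03,1.065407e-03
1299.140000,8.096099e-03,4.411241e-02,2.601128e-03,1.546299e-03
1312.557006,7.914352e-03,4.387746e-02,2.592865e-03,1.621159e-03
1332.490000,7.655804e-03,4.353412e-02,2.581404e-03,1.732374e-03
1368.630000,7.219349e-03,4.292834e-02,2.562871e-03,1.934015e-03
1408.010000,6.786429e-03,4.229159e-02,2.545552e-03,2.153734e-03
1425.668265,6.605353e-03,4.201358e-02,2.538638e-03,2.252257e-03
1548.527030,5.531531e-03,4.019706e-02,2.501932e-03,2.937741e-03
1596.210000,5.187416e-03,3.954259e-02,2.491823e-03,3.203785e-03
1681.973304,4.648290e-03,3.842847e-02,2.477710e-03,3.682297e-03
1826.919480,3.919795e-03,3.670839e-02,2.462115e-03,4.491016e-03
1984.356575,3.317214e-03,3.503731e-02,2.452310e-03,5.369428e-03
2155.361011,2.817312e-03,3.341567e-02,2.446279e-03,6.323538e-03
2341.101971,2.401333e-03,3.184383e-02,2.442645e-03,7.359869e-03
2521.400000,2.086910e-03,3.047568e-02,2.440668e-03,8.365832e-03
2542.849393,2.054113e-03,3.032204e-02,2.440497e-03,8.485508e-03
2754.010000,1.772699e-03,2.890110e-02,2.439281e-03,9.663667e-03
2761.982653,1.763369e-03,2.885049e-02,2.439248e-03,9.708150e-03
3000.000000,1.519131e-03,2.742922e-02,2.438534e-03,1.103616e-02
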
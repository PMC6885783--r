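# element=Cl Z=17 A=35.4530 k_edge_keV=2.8224 l3_edge_keV=0.2022
energy_keV,photoelectric,incoherent,coherent,pair
10.000000,7.063320e+01,1.849448e-01,7.907305e-01,0.000000e+00
10.861763,5.509911e+01,1.843606e-01,7.211342e-01,0.000000e+00
11.797789,4.293912e+01,1.837315e-01,6.531096e-01,0.000000e+00
12.814478,3.343085e+01,1.830546e-01,5.876554e-01,0.000000e+00
13.918782,2.600401e+01,1.823268e-01,5.256089e-01,0.000000e+00
15.118251,2.020900e+01,1.815450e-01,4.676012e-01,0.000000e+00
16.421085,1.569185e+01,1.807057e-01,4.140392e-01,0.000000e+00
17.836193,1.217422e+01,1.798057e-01,3.651142e-01,0.000000e+00
19.373249,9.437549e+00,1.788416e-01,3.208303e-01,0.000000e+00
21.042763,7.310419e+00,1.778098e-01,2.810467e-01,0.000000e+00
22.856150,5.658536e+00,1.767070e-01,2.455215e-01,0.000000e+00
24.825808,4.376825e+00,1.755297e-01,2.139533e-01,0.000000e+00
26.340000,3.639894e+00,1.746388e-01,1.935930e-01,0.000000e+00
26.965203,3.383160e+00,1.742745e-01,1.860134e-01,0.000000e+00
29.288964,2.613420e+00,1.729381e-01,1.613688e-01,0.000000e+00
30.970000,2.194676e+00,1.719885e-01,1.464306e-01,0.000000e+00
31.812977,2.017602e+00,1.715175e-01,1.396970e-01,0.000000e+00
34.554501,1.556746e+00,1.700097e-01,1.206937e-01,0.000000e+00
37.532278,1.200531e+00,1.684121e-01,1.040761e-01,0.000000e+00
40.766670,9.253796e-01,1.667224e-01,8.958389e-02,0.000000e+00
44.279789,7.129789e-01,1.649386e-01,7.697845e-02,0.000000e+00
48.095656,5.491145e-01,1.630591e-01,6.604220e-02,0.000000e+00
52.240360,4.227653e-01,1.610831e-01,5.657742e-02,0.000000e+00
53.160000,4.000443e-01,1.606536e-01,5.475024e-02,0.000000e+00
56.742239,3.253924e-01,1.590101e-01,4.840513e-02,0.000000e+00
59.540000,2.793585e-01,1.577585e-01,4.417767e-02,0.000000e+00
61.632073,2.503857e-01,1.568403e-01,4.136413e-02,0.000000e+00
66.943295,1.926324e-01,1.545746e-01,3.530992e-02,0.000000e+00
72.712218,1.481808e-01,1.522146e-01,3.011369e-02,0.000000e+00
78.978285,1.139785e-01,1.497627e-01,2.566117e-02,0.000000e+00
80.190000,1.085999e-01,1.493013e-01,2.491395e-02,0.000000e+00
80.997000,1.052018e-01,1.489962e-01,2.443414e-02,0.000000e+00
85.784339,8.766974e-02,1.472220e-01,2.185155e-02,0.000000e+00
93.176913,6.743746e-02,1.445964e-01,1.859630e-02,0.000000e+00
101.206551,5.188091e-02,1.418907e-01,1.581802e-02,0.000000e+00
109.928154,3.992092e-02,1.391101e-01,1.344930e-02,0.000000e+00
119.401351,3.072651e-02,1.362608e-01,1.143168e-02,0.000000e+00
121.780000,2.886730e-02,1.355715e-01,1.099638e-02,0.000000e+00
129.690913,2.365816e-02,1.333495e-01,9.714604e-03,0.000000e+00
140.510000,1.837038e-02,1.304752e-01,8.295882e-03,0.000000e+00
140.867192,1.822386e-02,1.303833e-01,8.254481e-03,0.000000e+00
153.006600,1.404526e-02,1.273699e-01,7.013829e-03,0.000000e+00
160.610000,1.205847e-02,1.255832e-01,6.374996e-03,0.000000e+00
166.192137,1.083153e-02,1.243172e-01,5.960491e-03,0.000000e+00
180.513955,8.359168e-03,1.212332e-01,5.066936e-03,0.000000e+00
196.069973,6.456445e-03,1.181260e-01,4.309645e-03,0.000000e+00
212.966551,4.991458e-03,1.150037e-01,3.668558e-03,0.000000e+00
223.200000,4.314882e-03,1.132272e-01,3.349674e-03,0.000000e+00
231.319213,3.862898e-03,1.118740e-01,3.126594e-03,0.000000e+00
244.700000,3.246925e-03,1.097445e-01,2.807052e-03,0.000000e+00
251.253438,2.992962e-03,1.087444e-01,2.669235e-03,0.000000e+00
272.905521,2.321900e-03,1.056220e-01,2.284157e-03,0.000000e+00
276.400000,2.233189e-03,1.051424e-01,2.230617e-03,0.000000e+00
284.300000,2.048831e-03,1.040816e-01,2.117063e-03,0.000000e+00
296.423499,1.803824e-03,1.025132e-01,1.960910e-03,0.000000e+00
302.850000,1.689857e-03,1.017096e-01,1.886018e-03,0.000000e+00
321.968169,1.403490e-03,9.942413e-02,1.690632e-03,0.000000e+00
344.280000,1.146566e-03,9.693841e-02,1.505219e-03,0.000000e+00
349.714183,1.093822e-03,9.636007e-02,1.465804e-03,0.000000e+00
356.010000,1.036762e-03,9.570246e-02,1.422600e-03,0.000000e+00
364.490000,9.661351e-04,9.483706e-02,1.368280e-03,0.000000e+00
379.851245,8.540142e-04,9.332580e-02,1.280023e-03,0.000000e+00
383.850000,8.277663e-04,9.294375e-02,1.258987e-03,0.000000e+00
411.100000,6.752429e-04,9.045563e-02,1.133810e-03,0.000000e+00
412.585406,6.680756e-04,9.032548e-02,1.127802e-03,0.000000e+00
443.900000,5.385214e-04,8.770142e-02,1.017256e-03,0.000000e+00
448.140475,5.237089e-04,8.736267e-02,1.004391e-03,0.000000e+00
486.759547,4.114535e-04,8.444041e-02,9.056220e-04,0.000000e+00
487.020000,4.108148e-04,8.442164e-02,9.050548e-04,0.000000e+00
511.000000,3.574389e-04,8.274233e-02,8.575465e-04,0.000000e+00
528.706666,3.240273e-04,8.156125e-02,8.277845e-04,0.000000e+00
574.268631,2.558208e-04,7.872730e-02,7.675314e-04,0.000000e+00
623.756956,2.025104e-04,7.594035e-02,7.218256e-04,0.000000e+00
636.990000,1.909261e-04,7.524024e-02,7.121995e-04,0.000000e+00
661.660000,1.716978e-04,7.398106e-02,6.965728e-04,0.000000e+00
677.510000,1.607604e-04,7.320186e-02,6.879203e-04,0.000000e+00
722.900000,1.344053e-04,7.108835e-02,6.679788e-04,0.000000e+00
735.895281,1.279950e-04,7.051308e-02,6.633640e-04,0.000000e+00
778.900000,1.096373e-04,6.869511e-02,6.507880e-04,0.000000e+00
799.311987,1.022233e-04,6.787510e-02,6.460196e-04,0.000000e+00
815.770000,9.675841e-05,6.723260e-02,6.426362e-04,0.000000e+00
867.380000,8.210927e-05,6.531790e-02,6.341903e-04,0.000000e+00
868.193708,8.190465e-05,6.528886e-02,6.340794e-04,0.000000e+00
943.011398,6.584535e-05,6.275525e-02,6.260682e-04,0.000000e+00
964.060000,6.215368e-05,6.208767e-02,6.244383e-04,0.000000e+00
1024.276598,5.311935e-05,6.027511e-02,6.208270e-04,3.193630e-06
1085.870000,4.574058e-05,5.855576e-02,6.183081e-04,8.951775e-05
1112.070000,4.305375e-05,5.786163e-02,6.174942e-04,1.262375e-04
1112.544928,4.300722e-05,5.784924e-02,6.174806e-04,1.269031e-04
1173.230000,3.762380e-05,5.631965e-02,6.160261e-04,2.119542e-04
1208.419894,3.494914e-05,5.547843e-02,6.153927e-04,2.612733e-04
1212.950000,3.462554e-05,5.537243e-02,6.153202e-04,2.676224e-04
1299.140000,2.923366e-05,5.344814e-02,6.142436e-04,3.884190e-04
1312.557006,2.850883e-05,5.316347e-02,6.141180e-04,4.072231e-04
1332.490000,2.748092e-05,5.274746e-02,6.139477e-04,4.351595e-04
1368.630000,2.575455e-05,5.201348e-02,6.136823e-04,4.858103e-04
1408.010000,2.405359e-05,5.124197e-02,6.134461e-04,5.410020e-04
1425.668265,2.334566e-05,5.090513e-02,6.133551e-04,5.657503e-04
1548.527030,1.919320e-05,4.870416e-02,6.129067e-04,7.379388e-04
1596.210000,1.788034e-05,4.791119e-02,6.127946e-04,8.047672e-04
1681.973304,1.584266e-05,4.656128e-02,6.126476e-04,9.249658e-04
1826.919480,1.313009e-05,4.447717e-02,6.125000e-04,1.128110e-03
1984.356575,1.092643e-05,4.245243e-02,6.124170e-04,1.348761e-03
2155.361011,9.129907e-06,4.048760e-02,6.123709e-04,1.588426e-03
2341.101971,7.660056e-06,3.858310e-02,6.123456e-04,1.848745e-03
2521.400000,6.566260e-06,3.692540e-02,6.123328e-04,2.101435e-03
2542.849393,6.453102e-06,3.673925e-02,6.123317e-04,2.131497e-03
2754.010000,5.490052e-06,3.501759e-02,6.123244e-04,2.427442e-03
2761.982653,5.458376e-06,3.495627e-02,6.123243e-04,2.438616e-03
3000.000000,4.635513e-06,3.323420e-02,6.123202e-04,2.772201e-03
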
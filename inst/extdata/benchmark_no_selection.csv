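feature,classifier,tp,tn,fp,fn,mse,accuracy,precision,f1,mcc,fm,error_rate,jaccard,csi
FCM,GMM,44,26,24,6,1.82e-04,70,64.706,74.576,0.429,0.755,30,59.459,52.706
FCM,DFA,48,26,24,2,2.00e-04,74,66.667,78.689,0.535,0.800,26,64.865,62.667
FCM,NLR,47,26,24,3,2.10e-04,73,66.197,77.686,0.507,0.789,27,63.514,60.197
FCM,BLDC,39,27,23,11,1.06e-04,66,62.903,69.643,0.330,0.700,34,53.425,40.903
FCM,LR,40,27,23,10,3.03e-05,67,63.492,70.796,0.352,0.713,33,54.795,43.492
FCM,KNN,34,26,24,16,1.82e-04,60,58.621,62.963,0.203,0.631,40,45.946,26.621
SDA,GMM,42,43,7,8,4.62e-06,85,85.714,84.848,0.700,0.849,15,73.684,69.714
SDA,DFA,46,40,10,4,6.98e-06,86,82.143,86.792,0.725,0.869,14,76.667,74.143
SDA,NLR,48,44,6,2,2.38e-06,92,88.889,92.308,0.843,0.924,8,85.714,84.889
SDA,BLDC,35,26,24,15,2.06e-04,61,59.322,64.220,0.224,0.644,39,47.297,29.322
SDA,LR,36,26,24,14,2.34e-04,62,60.000,65.455,0.245,0.657,38,48.649,32.000
SDA,KNN,28,27,23,22,1.75e-04,55,54.902,55.446,0.100,0.554,45,38.356,10.902
HILBERT,GMM,30,27,23,20,1.85e-04,57,56.604,58.252,0.140,0.583,43,41.096,16.604
HILBERT,DFA,47,26,24,3,2.01e-04,73,66.197,77.686,0.507,0.789,27,63.514,60.197
HILBERT,NLR,48,26,24,2,2.10e-04,74,66.667,78.689,0.535,0.800,26,64.865,62.667
HILBERT,BLDC,37,40,10,13,1.80e-05,77,78.723,76.289,0.541,0.763,23,61.667,52.723
HILBERT,LR,33,42,8,17,2.67e-05,75,80.488,72.527,0.508,0.729,25,56.897,46.488
HILBERT,KNN,28,27,23,22,1.68e-04,55,54.902,55.446,0.100,0.554,45,38.356,10.902
FFT,GMM,33,42,8,17,2.77e-05,75,80.488,72.527,0.508,0.729,25,56.897,46.488
FFT,DFA,45,28,22,5,7.31e-05,73,67.164,76.923,0.489,0.777,27,62.500,57.164
FFT,NLR,45,29,21,5,4.33e-05,74,68.182,77.586,0.507,0.783,26,63.380,58.182
FFT,BLDC,34,34,16,16,3.97e-05,68,68.000,68.000,0.360,0.680,32,51.515,36.000
FFT,LR,29,29,21,21,7.87e-05,58,58.000,58.000,0.160,0.580,42,40.845,16.000
FFT,KNN,26,41,9,24,1.34e-04,67,74.286,61.176,0.356,0.622,33,44.068,26.286
DCT,GMM,36,41,9,14,1.73e-05,77,80.000,75.789,0.543,0.759,23,61.017,52.000
DCT,DFA,45,37,13,5,1.19e-05,82,77.586,83.333,0.648,0.836,18,71.429,67.586
DCT,NLR,46,29,21,4,3.59e-05,75,68.657,78.632,0.532,0.795,25,64.789,60.657
DCT,BLDC,37,36,14,13,2.68e-05,73,72.549,73.267,0.460,0.733,27,57.813,46.549
DCT,LR,31,29,21,19,6.92e-05,60,59.615,60.784,0.200,0.608,40,43.662,21.615
DCT,KNN,29,26,24,21,2.21e-04,55,54.717,56.311,0.100,0.563,45,39.189,12.717
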
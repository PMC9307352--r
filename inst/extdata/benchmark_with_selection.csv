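feature,classifier,tp,tn,fp,fn,mse,accuracy,precision,f1,mcc,fm,error_rate,jaccard,csi
FCM,GMM,30,36,14,20,4.58e-05,66,68.182,63.830,0.322,0.640,34,46.875,28.182
FCM,DFA,28,41,9,22,5.41e-05,69,75.676,64.368,0.394,0.651,31,47.458,31.676
FCM,NLR,30,33,17,20,5.54e-05,63,63.830,61.856,0.260,0.619,37,44.776,23.830
FCM,BLDC,36,29,21,14,4.82e-05,65,63.158,67.290,0.303,0.674,35,50.704,35.158
FCM,LR,44,33,17,6,2.36e-05,77,72.131,79.279,0.554,0.797,23,65.672,60.131
FCM,KNN,29,27,23,21,0.000125,56,55.769,56.863,0.120,0.569,44,39.726,13.769
SDA,GMM,42,34,16,8,2.45e-05,76,72.414,77.778,0.527,0.780,24,63.636,56.414
SDA,DFA,41,27,23,9,9.06e-05,68,64.063,71.930,0.375,0.725,32,56.164,46.063
SDA,NLR,26,27,23,24,0.000262,53,53.061,52.525,0.060,0.525,47,35.616,5.061
SDA,BLDC,43,29,21,7,4.18e-05,72,67.188,75.439,0.458,0.760,28,60.563,53.188
SDA,LR,34,29,21,16,5.55e-05,63,61.818,64.762,0.261,0.648,37,47.887,29.818
SDA,KNN,28,27,23,22,0.000142,55,54.902,55.446,0.100,0.554,45,38.356,10.902
HILBERT,GMM,29,34,16,21,5.53e-05,63,64.444,61.053,0.261,0.611,37,43.939,22.444
HILBERT,DFA,49,27,23,1,0.000105,76,68.056,80.328,0.579,0.817,24,67.123,66.056
HILBERT,NLR,44,35,15,6,1.71e-05,79,74.576,80.734,0.590,0.810,21,67.692,62.576
HILBERT,BLDC,45,37,13,5,1.3e-05,82,77.586,83.333,0.648,0.836,18,71.429,67.586
HILBERT,LR,44,26,24,6,0.000192,70,64.706,74.576,0.429,0.755,30,59.459,52.706
HILBERT,KNN,33,37,13,17,3.43e-05,70,71.739,68.750,0.401,0.688,30,52.381,37.739
FFT,GMM,29,42,8,21,4.53e-05,71,78.378,66.667,0.435,0.674,29,50.000,36.378
FFT,DFA,45,41,9,5,6.42e-06,86,83.333,86.538,0.722,0.866,14,76.271,73.333
FFT,NLR,35,27,23,15,9.02e-05,62,60.345,64.815,0.243,0.650,38,47.945,30.345
FFT,BLDC,29,27,23,21,0.000163,56,55.769,56.863,0.120,0.569,44,39.726,13.769
FFT,LR,35,26,24,15,0.000187,61,59.322,64.220,0.224,0.644,39,47.297,29.322
FFT,KNN,27,31,19,23,0.000115,58,58.696,56.250,0.161,0.563,42,39.130,12.696
DCT,GMM,46,42,8,4,4.64e-06,88,85.185,88.462,0.762,0.885,12,79.310,77.185
DCT,DFA,46,27,23,4,8.89e-05,73,66.667,77.311,0.497,0.783,27,63.014,58.667
DCT,NLR,45,28,22,5,7.92e-05,73,67.164,76.923,0.489,0.777,27,62.500,57.164
DCT,BLDC,37,36,14,13,2.28e-05,73,72.549,73.267,0.460,0.733,27,57.813,46.549
DCT,LR,34,42,8,16,2.42e-05,76,80.952,73.913,0.527,0.742,24,58.621,48.952
DCT,KNN,28,33,17,22,6.8e-05,61,62.222,58.947,0.221,0.590,39,41.791,18.222
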
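method,texture,max,right,producer
Supervised KNN 7 classes,no,0.51,0.83,0.96
Supervised KNN 7 classes,yes,0.52,0.82,0.86
Supervised SVM 7 classes,no,0.49,0.77,0.87
Supervised SVM 7 classes,yes,0.54,0.85,0.92
Supervised Bayesian 7 classes,no,0.62,0.90,0.73
Supervised Bayesian 7 classes,yes,0.57,0.86,0.88
Hierarchical with KNN,yes,0.51,0.80,0.78
Hierarchical with SVM,yes,0.53,0.85,0.78
Hierarchical with Bayesian,yes,0.53,0.85,0.84
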
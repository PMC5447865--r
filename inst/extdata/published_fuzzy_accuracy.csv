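method,texture,max,right,max_right,producer
Unsupervised 12 clusters,no,0.36,0.68,0.32,0.96
Unsupervised 12 clusters,yes,0.34,0.70,0.36,1.00
Unsupervised 18 clusters,no,0.35,0.68,0.33,0.98
Unsupervised 18 clusters,yes,0.35,0.71,0.36,1.00
Supervised KNN 3 classes,no,0.45,0.81,0.36,0.66
Supervised KNN 3 classes,yes,0.44,0.77,0.33,0.64
Supervised KNN 7 classes,no,0.45,0.78,0.33,0.66
Supervised KNN 7 classes,yes,0.45,0.77,0.33,0.68
Supervised SVM 3 classes,no,0.23,0.67,0.44,0.44
Supervised SVM 3 classes,yes,0.40,0.66,0.26,0.56
Supervised SVM 7 classes,no,0.35,0.66,0.31,0.64
Supervised SVM 7 classes,yes,0.45,0.73,0.28,0.90
Supervised Bayesian 3 classes,no,0.44,0.73,0.29,0.82
Supervised Bayesian 3 classes,yes,0.44,0.71,0.27,0.88
Supervised Bayesian 7 classes,no,0.52,0.83,0.31,0.60
Supervised Bayesian 7 classes,yes,0.48,0.76,0.32,0.76
Hierarchical with KNN,yes,0.40,0.69,0.29,0.76
Hierarchical with SVM,yes,0.33,0.63,0.30,0.58
Hierarchical with Bayesian,yes,0.46,0.76,0.30,0.74
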
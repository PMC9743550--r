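clustering,feature_engineering,ari,dice,exims,ari_rank,dice_rank,exims_rank,rank_sum,d000,d111
Spectral,UMAP,0.2792,0.4844,0.5891,17,16,20,53,0.8122,0.9768
Spatial,UMAP,0.0000,0.0000,1.0000,19.5,19,2.5,41,1.0000,1.4142
Spectral,Xception,0.0000,0.0000,1.0000,19.5,19,2.5,41,1.0000,1.4142
K-means,Knee PCA,0.2723,0.0000,1.0000,18,19,2.5,39.5,1.0364,1.2368
K-means,Xception,0.3098,0.4577,0.9197,16,17,8,41,1.0730,0.8814
K-means,EXIMS PCA,0.4827,0.5129,0.8323,12,14,9,35,1.0903,0.7300
Spectral,EXIMS PCA,0.5447,0.7418,0.6449,8,8,18,34,1.1237,0.6325
K-means,none,0.3364,0.5043,0.9712,15,15,6,36,1.1449,0.8288
K-means,UMAP,0.5231,0.7238,0.7225,10,10,13,33,1.1487,0.6170
Spatial,Knee PCA,0.4985,0.7065,0.7639,11,11,10,32,1.1537,0.6272
DiviK,EXIMS PCA,0.6082,0.7765,0.6383,4,5,19,28,1.1749,0.5782
Spectral,none,0.5906,0.7966,0.6520,5,4,17,26,1.1868,0.5745
DiviK,Knee PCA,0.5567,0.7540,0.7289,7,7,12,26,1.1873,0.5749
DiviK,Xception,0.4203,0.6429,0.9395,14,13,7,34,1.2136,0.6835
Spatial,none,0.5617,0.7720,0.7587,6,6,11,23,1.2195,0.5498
DiviK,UMAP,0.6534,0.8369,0.6568,2,3,16,21,1.2485,0.5143
Spatial,Xception,0.6517,0.8465,0.6851,3,2,15,20,1.2691,0.4940
Spectral,Knee PCA,0.4594,0.6897,0.9891,13,12,5,30,1.2904,0.6235
Spatial,EXIMS PCA,0.7035,0.8672,0.6977,1,1,14,16,1.3167,0.4438
DiviK,none,0.5433,0.7372,1.0000,9,9,2.5,20.5,1.3560,0.5269
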
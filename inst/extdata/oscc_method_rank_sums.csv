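method,rand_rank_sum,dice_rank_sum,exims_rank_sum,scalability_rank_sum,total
Spectral,62.5,59,62.5,72.5,256.5
K-means,71,75,38.5,32.5,217
Spatial,40.5,39,52.5,72.5,204.5
DiviK,36,37,56.5,32.5,162
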
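"fruit_id","w_top_mm","h_top_mm","w_side_mm","h_side_mm","volume_ml"
"fruit_001",70.898,84.097,70.43,84.666,294.775
"fruit_002",56.009,52.002,55.626,55.061,88.831
"fruit_003",73.058,64.463,72.441,76.364,217.251
"fruit_004",77.364,62.28,78.078,76.432,231.315
"fruit_005",73.998,80.802,74.805,68.503,243.641
"fruit_006",79.896,76.837,80.365,65.266,252.448
"fruit_007",69.776,76.546,70.425,76.126,218.197
"fruit_008",70.348,71.839,70.35,62.668,189.413
"fruit_009",64.59,63.85,64.932,66.863,143.368
"fruit_010",49.064,49.695,49.109,49.882,66.628
"fruit_011",84.007,87.558,83.049,73.07,317.04
"fruit_012",86.936,88.088,87.946,73.246,351.905
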
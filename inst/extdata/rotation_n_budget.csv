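treatment,year,cum_kg_n_ha,catch_crop_n,fertilizer_n,plant_n
C4-CC+N,2011,0.27,0,120,138.6
O4+CC+N,2011,0.79,40.7,100,92.0
O4+CC-N,2011,0.80,32.3,0,88.8
O4-CC+N,2011,0.20,0,100,78.1
O4-CC-N,2011,0.25,0,0,NA
C4-CC+N,2012,0.96,0,120,148.0
O4+CC+N,2012,1.39,38.0,132,92.9
O4+CC-N,2012,0.91,32.2,0,85.8
O4-CC+N,2012,0.28,0,132,75.1
O4-CC-N,2012,0.18,0,0,NA
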
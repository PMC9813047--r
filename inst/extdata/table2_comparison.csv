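age_band,hospital_pct,hospital_upper_pct,hospital_lower_pct,scc_pct,scc_upper_pct,scc_lower_pct
< 50,0.112,0.120,0.106,1.088,1.314,0.213
50-59,0.419,0.432,0.406,1.412,1.705,0.277
60-69,0.360,0.372,0.349,2.090,2.524,0.410
70-79,0.310,0.320,0.300,2.359,2.848,0.463
> 79,0.120,0.126,0.114,4.162,5.025,0.816
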
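age_band,ci_low_pct,ci_high_pct
0-4,0.00016,0.0026
5-9,0.0031,0.0081
10-14,0.0038,0.0094
15-19,0.003,0.0077
20-24,0.012,0.019
25-29,0.038,0.049
30-34,0.096,0.11
35-39,0.18,0.21
40-44,0.33,0.35
45-49,0.4,0.43
50-54,0.41,0.44
55-59,0.4,0.43
60-64,0.36,0.39
65-69,0.33,0.36
70-74,0.33,0.35
75-79,0.27,0.29
80-84,0.2,0.21
85-89,0.11,0.13
Above 90,0.033,0.04
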
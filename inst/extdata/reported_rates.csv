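quantity,value,age_band
inpatient_fce_rate_per_100k,11.3,
outpatient_rate_per_100k,1.19,
total_fces,35078,
total_admissions,28517,
peak_incidence_per_100k,27.9,75-79
peak_incidence_sd,1.89,75-79
peak_fce_count_mean,590,65-69
peak_fce_count_sd,42.4,65-69
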
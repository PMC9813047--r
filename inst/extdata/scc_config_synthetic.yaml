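# Example run configuration with a SYNTHETIC (reconstructed) SCC block.
#
# The SCC-to-DCM conversion rates and the age-stratified SCC prevalence
# curve are external literature inputs, not quantities this package
# estimates. The source studies are not bundled, so the values below are a
# reconstruction: the pooled conversion rate is the published pooled DCM
# prevalence (2.3%) over a pooled SCC prevalence of 24.4%, the bound
# ratios (upper/pooled ~ 1.2075, lower/pooled ~ 0.1961) and the curve are
# back-calculated from the published coarse-band SCC-derived prevalence
# column. Replace with values taken directly from the literature for any
# substantive use.
icd_codes: ["M47.1", "M50.0", "M99.3", "M99.4", "M99.5"]
years: [2012, 2013, 2014, 2015, 2016, 2017, 2018]
smr: 1.18
ci_method: poisson
fill_missing: error
seed: 1
conversion:
  pooled: 0.0943
  lower: 0.018494
  upper: 0.113867
scc_curve:
  "< 50": 0.115376
  "50-59": 0.149735
  "60-69": 0.221633
  "70-79": 0.250159
  "> 79": 0.441357
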
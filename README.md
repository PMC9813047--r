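# dcmprev

Age-stratified prevalence modelling for degenerative cervical myelopathy
(DCM), a progressive spinal-cord injury caused by degenerative change in
the cervical spine that is thought to be substantially underdiagnosed,
especially among the elderly. The package is aimed at epidemiologists and
health-services researchers working with aggregate hospital-activity
extracts (counts by age band and year) who want defensible prevalence
estimates and a quantified comparison against imaging-based expectations.

## What it computes

Two independent prevalence estimates, harmonised and compared:

**Hospital route.** Per 5-year age band, incidence per 100,000
person-years from annual case counts and population denominators, then
the steady-state extrapolation

    P = I · D

with disease duration D equal to remaining life expectancy at the band
midpoint, read from an abridged period life table whose central death
rates are inflated by the disease's standardised mortality ratio
(m'_x = SMR × m_x, with q_x = n·m'_x / (1 + (n − a_x)·m'_x); SMR = 1.18
for DCM). Confidence intervals propagate the Poisson uncertainty of the
band's event count through the linear P = I·D map.

**Imaging route.** An age-stratified prevalence curve of spinal cord
compression (SCC — necessary but not sufficient for DCM) multiplied by a
pooled SCC→DCM conversion rate with its lower/upper bounds.

Both are reformatted onto standardised coarse age groups (< 50, 50–59,
60–69, 70–79, > 79; coarse values are unweighted means of constituent
strata) and compared band-by-band: mismatch ratios, interval-overlap
flags, year-of-birth cohort tables with descriptive within-band slopes,
and the outpatient/inpatient incidence contrast. A synthetic-registry
generator (log-quadratic incidence curve, logistic population pyramid,
Gompertz–Makeham mortality, Poisson counts) provides known ground truth
for end-to-end parameter-recovery testing.

## Worked example

Reconstruction from the published summary tables shipped with the
package (`hes_table1()` is the fine-band hospital-derived prevalence
table, points taken as interval midpoints; proportions internally,
percent in reports):

```r
library(dcmprev)

t1 <- hes_table1()
round(100 * mean_over_bands(t1)$mean, 3)
#> [1] 0.193

as.data.frame(rebin_prevalence(t1))[, c("age_band", "point")]
#>   age_band      point
#> 1     < 50 0.00113093
#> 2    50-59 0.00420000
#> 3    60-69 0.00360000
#> 4    70-79 0.00310000
#> 5     > 79 0.00120500
```

The mean prevalence across the 19 strata is 0.193% and the coarse
hospital column (0.420%, 0.360%, 0.310%, 0.1205%) matches the published
values to their printed precision. Comparing against the SCC-derived
estimates:

```r
t2 <- hes_table2()
cmp <- compare_prevalence(t2$hospital, t2$scc)
cmp[, c("age_band", "mismatch_ratio", "overlap")]
#>   age_band mismatch_ratio overlap
#> 1     < 50       9.714286   FALSE
#> 2    50-59       3.369928    TRUE
#> 3    60-69       5.805556   FALSE
#> 4    70-79       7.609677   FALSE
#> 5     > 79      34.683333   FALSE
```

The two routes' bounds overlap only at ages 50–59, and the SCC-derived
estimate exceeds the hospital-derived one ~35-fold above age 79 — the
widening diagnostic gap with age.

Fitting the model on a synthetic registry with known truth:

```r
sim <- simulate_registry(registry_truth(seed = 1))
fit <- dcm_prevalence(sim$counts, sim$population, sim$life_table, smr = 1.18)
fit
#> Hospital-registry prevalence model (P = I * D)
#>   bands: 19; years per band: 7; SMR: 1.18; CI: poisson
#>   total events: 29394
#>   peak prevalence: 0.284% at 70-74
#>   mean prevalence across bands: 0.089% (sd 0.105)
```

`coef(fit)` returns band prevalences as proportions, `summary(fit)` the
full band table with incidence, duration and intervals, `plot(fit)` the
age profile, and `sim$truth_report` the generator's truth for recovery
checks. `run_pipeline()` drives the same analysis from CSV inputs and a
YAML config to an output directory of tables, plots and a reproducibility
manifest; `example_config_path()` points at a documented example config
whose SCC block is a labelled reconstruction.

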
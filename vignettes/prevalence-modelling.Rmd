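---
title: "Modelling age-stratified DCM prevalence from hospital activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age-stratified DCM prevalence from hospital activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmprev)
```

## The problem

Degenerative cervical myelopathy (DCM) is a progressive spinal-cord injury
caused by degenerative change in the cervical spine. It is widely
under-recognised: radiological spinal cord compression (SCC), which is
necessary but not sufficient for DCM, is common in the ageing spine, yet
hospital activity coded to DCM is comparatively rare. `dcmprev` estimates
the age-stratified prevalence of DCM along two independent routes and
quantifies the gap between them:

* the **hospital route** — registry case counts turned into incidence,
  extrapolated to prevalence via disease duration; and
* the **imaging route** — an age-stratified SCC prevalence curve scaled by
  the proportion of people with SCC who also have DCM (the *conversion
  rate*).

Where the imaging route sits far above the hospital route, and the gap
widens with age, underdiagnosis in older age groups is one candidate
explanation; the package computes the tables and diagnostics needed to
examine that hypothesis, without attempting a causal decomposition.

## The hospital model

For each 5-year age band $a$ and survey (fiscal) year $t$, the incidence
rate per 100,000 person-years is

$$ I_{a,t} = \frac{\text{events}_{a,t}}{\text{persons}_{a,t}} \times 10^5, $$

summarised across years with equal weight as mean ± sample SD. Rates are
computed per year and then averaged — not pooled over person-years —
matching how annual registry extracts are conventionally presented; with
seven survey years the two differ only through population drift.

Prevalence uses the steady-state identity $P = I \cdot D$. Because the
underlying degenerative process is incurable, duration $D$ is taken as
remaining life expectancy at the band's representative age, read from an
abridged period life table whose central death rates have been inflated by
the disease's standardised mortality ratio (SMR, default 1.18):

$$ m_x' = \mathrm{SMR} \times m_x, \qquad
   q_x = \frac{n\,m_x'}{1 + (n - a_x)\,m_x'} . $$

The SMR multiplies central death rates $m_x$, not death probabilities
$q_x$: an SMR is a ratio of rates, and scaling $q_x$ can exceed 1. The
separation factor is $a_x = n/2$ except in the age-0 interval
($a_x = 0.3\,n$), the standard abridged-table convention; the terminal
open interval takes $q_x = 1$ and $L_x = l_x / m_x$. `ex` is invariant to
the radix. With constant hazard $\mu$ the construction converges to the
exponential closed form $e_0 = 1/\mu$ as interval widths shrink, which the
tests exercise at widths 5, 1 and 0.25 years.

Representative ages are band midpoints (52 for 50–54); an open band
anchors at its lower edge (90 for "Above 90"), the least-assumption
choice since the age distribution inside an open band is unknown.
Life expectancy between table rows is interpolated linearly — smooth,
monotone between rows, and easy to verify.

```{r lifetable}
sched <- data.frame(age = 0:100, mx = 5e-4 + 2.5e-5 * exp(0.1 * (0:100)))
adj <- apply_smr(sched, smr = 1.18)
c(e0 = adj$ex[1], e70 = life_expectancy_at(adj, 70))
```

### Confidence intervals

The published methodology for prevalence intervals is cited but not
reproduced in the source tables, so the package had a genuinely open
choice. The default is a normal-approximation Poisson interval on the
band's total event count, propagated through the linear $P = I D$ map in
relative terms, $P\,(1 \pm z_{0.975}/\sqrt{E})$. This choice reproduces
the relative widths of the published fine-band intervals (roughly ±3.5%
at 50–54), whereas a binomial interval on the population denominator is
about half as wide. The binomial (Wald-on-proportion) form remains
available via `ci_method = "binomial"` for sensitivity analysis. With
zero events the interval degenerates to $(0, P)$ with a warning rather
than an error, since empty young bands are routine in rare-disease
extracts.

### Reformatting and summaries

Comparison happens on standardised coarse groups (< 50, 50–59, 60–69,
70–79, > 79). A coarse value is the **unweighted** mean of its
constituent fine-band values (bounds treated the same way; events
summed). Unweighted averaging — not population weighting — is what
reproduces the published coarse table exactly from the published fine
table, and the "mean prevalence across all age groups" is likewise the
unweighted mean over the 19 fine strata. Prevalence is carried internally
as a proportion in $[0,1]$ and rendered as a percentage only in reports,
avoiding unit drift.

```{r printed}
t1 <- hes_table1()               # published fine-band table, CI midpoints
round(100 * mean_over_bands(t1)$mean, 3)
as.data.frame(rebin_prevalence(t1))[, c("age_band", "point")]
```

The published fine table prints only interval bounds; when reconstructing
from it, the package uses the interval midpoint as the point estimate.
Whether the original bounds were symmetric on the proportion or the log
scale is not stated; at these widths the distinction is below the printed
precision.

## The imaging route

Given an SCC prevalence curve $s_a$ (a config input on the curve's native
bands) and conversion rates $(c_{\mathrm{lower}}, c_{\mathrm{pooled}},
c_{\mathrm{upper}})$, the DCM estimates are $s_a \cdot c$ for each of the
three rates. A single age-constant conversion rate is a modelling
assumption, visible in the output as band-independent bound-to-point
ratios; the interface takes the rates per call, so age-varying rates
could be supplied band-wise without structural change.

The curve and rates are literature inputs the package deliberately does
not hard-code. The shipped example config
(`scc_config_synthetic.yaml`) is labelled **synthetic**: its pooled rate
is a published pooled DCM prevalence (2.3%) over a pooled SCC prevalence
of 24.4%, and its curve and bound ratios are back-calculated from the
published coarse outputs, so it reproduces them by construction. It
demonstrates the mechanics and pins the constant-ratio property
(upper/pooled ≈ 1.207, lower/pooled ≈ 0.196); it is not a substitute for
sourcing the original study values.

## Comparison, cohorts, outpatient contrast

`compare_prevalence()` reports, per coarse band, the mismatch ratio
(SCC-derived over hospital-derived point) and an overlap flag — whether
the hospital confidence interval intersects the SCC bound interval, the
literal reading of "upper and lower bounds overlap". On the published
tables the flag is true only at 50–59, and the > 79 mismatch ratio is
about 35.

```{r compare}
t2 <- hes_table2()
cmp <- compare_prevalence(t2$hospital, t2$scc)
cmp[, c("age_band", "mismatch_ratio", "overlap")]
```

`cohort_table()` reshapes per-year, per-band prevalence into the long
format behind age–period–cohort graphs (birth year = survey year minus
band midpoint, rounded). `cohort_slopes()` fits, within each age band,
the least-squares slope of prevalence on birth year: a descriptive
diagnostic, not an identified age–period–cohort decomposition, which the
seven-year survey window cannot support. On age-only simulations the
slopes are zero; an injected multiplicative birth-cohort effect shows up
with its sign. Note the published birth-year span (1925–2019) is not an
exact function of the printed band midpoints; the package reports the
span its own conventions produce rather than forcing the printed one.

`outpatient_ratio()` contrasts the all-ages outpatient attendance rate
with the inpatient episode rate (published values: 1.19 vs 11.3 per
100,000/year, ratio ≈ 0.105), the check that outpatient-only activity
cannot close the mismatch.

## The synthetic registry

Real extracts cannot ship with the package, so every downstream stage is
testable against `registry_truth()` / `simulate_registry()`, a generator
whose defaults emulate the published study conditions:

* **incidence**: log-quadratic in age,
  $r(a) = r_{\max} \exp\!\big(-((a - a_{\max})/w)^2\big)$ with
  $r_{\max} = 27.9$ per 100,000 person-years at $a_{\max} = 77$ (the
  published peak band's midpoint) and width $w = 18$ years, chosen so
  that mid-life rates are an order of magnitude below the peak;
* **population**: a logistic pyramid, ~3.6 million persons per young
  5-year band tapering through old age (loosely England-like), growing
  0.5% per year from fiscal 2012;
* **mortality**: Gompertz–Makeham
  $m_x = A + B e^{\theta x}$ with $A = 5 \times 10^{-4}$,
  $B = 2.5 \times 10^{-5}$, $\theta = 0.1$ per year, giving a
  period life expectancy near 80 years;
* **SMR** 1.18; seven fiscal years 2012–2018; counts Poisson with an
  optional overdispersion multiplier (off by default, matching the
  simple-rate treatment of the counts); an FCE:admission inflation
  factor of 1.23 (the ratio of the published national totals) and an
  outpatient fraction of 0.105 relate the three care settings.

Band-level truth is evaluated at the band midpoint, the same convention
the estimator uses, so generator and pipeline share one definition of
truth and parameter-recovery tests compare like with like.
`truth_report()` exposes it.

What the generator does **not** emulate: patient-level structure
(readmissions, consultant changes beyond the fixed inflation factor),
coding sensitivity/specificity, small-count suppression (available only
as an explicit zero-fill switch in the reader), secular trends in
incidence, and sex structure. Passing recovery tests therefore
demonstrate the estimator's correctness under the stated sampling model,
not robustness to those real-data features.

```{r recovery}
sim <- simulate_registry(registry_truth(seed = 1))
fit <- suppressWarnings(dcm_prevalence(sim$counts, sim$population,
                                       sim$life_table, smr = 1.18))
merge(as.data.frame(fit)[, c("age_band", "point")],
      sim$truth_report[, c("age_band", "true_prevalence")])[c(11, 15), ]
```

### Problem sizes and tolerances in the tests

The recovery suite uses the default scenario (≥ $10^6$ persons per band,
7 years) over 100 replicate seeds, asserting band incidence within 3
Monte-Carlo standard errors of truth and prevalence within 1% relative.
The relative criterion is assessed on bands with at least ~50 expected
events per year (midpoints 45 and above under the default curve): below
that the Monte-Carlo noise floor exceeds 1% and a relative criterion
stops being informative — the near-empty young bands are instead covered
by the 3-SE incidence check, which degenerates gracefully with the
signal. Single-run examples use a 5% band. Monte-Carlo distributional
checks use 200–300 replicates, enough to separate Poisson from
overdispersed spread at the simulated rates while keeping the default
suite fast.

## Degenerate inputs and numerical choices

* Missing count cells are an error by default; `fill_missing = "zero"`
  opts into treating absence as suppression-zero, never silently.
* `P = I\,D > 1` is capped at 1 with a warning (unreachable under
  realistic inputs, but the cap keeps the proportion invariant honest).
* An all-zero mortality schedule, a non-positive terminal rate, negative
  hazards, or abridged rates high enough to push $q_x$ over 1 are
  errors, not clamps.
* Fiscal years are stored as their starting calendar year (2012 for
  2012–13), a single sortable key.
* Dash variants and whitespace in band labels are normalised before
  parsing; the original label survives verbatim for display.
* All randomness flows through one integer seed; generator functions
  restore the caller's RNG state.

## Known limitations

The steady-state $P = I D$ identity ignores demographic flow between
bands and secular incidence trends; duration-as-life-expectancy assumes
onset at the band's representative age and no cure; the hospital route
measures *hospital-diagnosed* disease, so its gap to the imaging route
conflates underdiagnosis with case-ascertainment differences — which is
precisely the quantity of interest, but one the package measures rather
than explains. The life-table constants ($a_x$ conventions, the exact
$q_x$–$m_x$ relation used by any particular published table) vary
slightly between statistical offices; the package's standard choices can
differ from a specific published table in the second decimal of $e_x$.
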
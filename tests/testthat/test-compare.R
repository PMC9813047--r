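test_that("comparison rows carry ratios and interval-overlap flags", {
  h <- prevalence_points(c("a", "b"), c(0.01, 0.02),
                         c(0.009, 0.018), c(0.011, 0.022))
  # identical estimates: ratio 1, overlap everywhere
  cmp <- compare_prevalence(h, {
    s <- h; s$source <- "scc_pooled"; s
  })
  expect_equal(cmp$mismatch_ratio, c(1, 1))
  expect_true(all(cmp$overlap))

  # disjoint intervals: no overlap, ratio as quotient
  s <- prevalence_points(c("a", "b"), c(0.05, 0.025),
                         c(0.04, 0.0221), c(0.06, 0.03),
                         source = "scc_pooled")
  cmp2 <- compare_prevalence(h, s)
  expect_equal(cmp2$mismatch_ratio, c(5, 1.25))
  expect_equal(cmp2$overlap, c(FALSE, FALSE))

  # overlap is symmetric under swapping interval roles
  cmp3 <- compare_prevalence(
    prevalence_points(c("a", "b"), s$point, s$ci_low, s$ci_high),
    {
      x <- h; x$source <- "scc_pooled"; x
    })
  expect_equal(cmp3$overlap, cmp2$overlap)

  # and invariant under common rescaling
  scale2 <- function(p) {
    p$point <- p$point * 2; p$ci_low <- p$ci_low * 2
    p$ci_high <- p$ci_high * 2; p
  }
  expect_equal(compare_prevalence(scale2(h), scale2(s))$overlap, cmp2$overlap)

  expect_error(compare_prevalence(h, prevalence_points("c", 0.1,
                                                       source = "scc_pooled")),
               "different band schemes")
})

test_that("published coarse comparison overlaps only at ages 50-59", {
  t2 <- hes_table2()
  cmp <- compare_prevalence(t2$hospital, t2$scc)
  expect_equal(cmp$age_band[cmp$overlap], "50-59")
  expect_equal(cmp$mismatch_ratio[cmp$age_band == "> 79"],
               4.162 / 0.120, tolerance = 1e-10)
})

test_that("birth years subtract the band midpoint from the survey year", {
  expect_equal(birth_year(2012, age_band(50, 54)), 1960L)
  expect_equal(birth_year(2019, age_band(85, 89)), 1932L)
  expect_equal(birth_year(2015, age_band(90, Inf)), 1925L)
  # span of the full survey-year x band grid brackets the early 1920s to
  # the survey period itself
  yrs <- 2012:2019
  bys <- unlist(lapply(fine_bands(), function(b) birth_year(yrs, b)))
  expect_lte(min(bys), 1925)
  expect_gte(max(bys), 2012)
})

test_that("cohort tables are lossless and diagnose cohort effects", {
  bands <- fine_bands()
  yrs <- 2012:2018
  grid <- expand.grid(year = yrs, age_band = band_labels(bands),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mids <- vapply(bands, band_midpoint, numeric(1))
  age <- mids[match(grid$age_band, band_labels(bands))]

  # age-only prevalence: within every band the cohort slope is exactly 0
  grid$prevalence <- 0.004 * exp(-((age - 70) / 20)^2)
  ct <- cohort_table(grid, bands)
  expect_equal(ct$birth_year, ct$survey_year - as.integer(round(ct$midpoint_age)))
  # losslessness: regrouping recovers the input cells
  back <- ct[match(paste(grid$year, grid$age_band),
                   paste(ct$survey_year, ct$age_band)), ]
  expect_equal(back$prevalence, grid$prevalence)
  sl <- cohort_slopes(ct)
  expect_true(all(abs(sl$slope) < 1e-12))

  # injected cohort effect: 2% prevalence rise per later birth year
  grid2 <- grid
  by <- grid2$year - age
  grid2$prevalence <- grid$prevalence * (1.02 ^ (by - 1950))
  sl2 <- cohort_slopes(cohort_table(grid2, bands))
  expect_true(all(sl2$slope > 0))

  # and the opposite sign when prevalence falls with birth year
  grid3 <- grid
  grid3$prevalence <- grid$prevalence * (0.98 ^ (by - 1950))
  sl3 <- cohort_slopes(cohort_table(grid3, bands))
  expect_true(all(sl3$slope < 0))
})

test_that("outpatient/inpatient contrast is a guarded quotient", {
  expect_equal(outpatient_ratio(1.19, 11.3), 1.19 / 11.3)
  expect_equal(outpatient_ratio(5, 5), 1)
  expect_equal(outpatient_ratio(0, 3), 0)
  expect_error(outpatient_ratio(1, 0), "positive")
})
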
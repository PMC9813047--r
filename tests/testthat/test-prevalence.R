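test_that("P = I * D extrapolation is linear, capped and unit-correct", {
  expect_equal(extrapolate_prevalence(0, 10), 0)
  expect_equal(extrapolate_prevalence(27.9, 10), 0.00279)
  # linear in each argument
  expect_equal(extrapolate_prevalence(2 * 27.9, 10),
               2 * extrapolate_prevalence(27.9, 10))
  expect_equal(extrapolate_prevalence(27.9, 30),
               3 * extrapolate_prevalence(27.9, 10))
  expect_warning(p <- extrapolate_prevalence(90000, 50), "capping")
  expect_equal(p, 1)
  expect_error(extrapolate_prevalence(-1, 5), "non-negative")
})

test_that("Poisson-relative intervals track total events", {
  ci <- prevalence_ci(0.01, 100)
  expect_equal(ci$ci_low, 0.00804, tolerance = 1e-4)
  expect_equal(ci$ci_high, 0.01196, tolerance = 1e-4)
  # relative half-width scales as 1/sqrt(events)
  wide <- prevalence_ci(0.01, 25)
  expect_equal((wide$ci_high - wide$ci_low) / (ci$ci_high - ci$ci_low),
               sqrt(100 / 25))
  narrow <- prevalence_ci(0.01, 1e8)
  expect_lt(narrow$ci_high - narrow$ci_low, 1e-5)
  # zero events: degenerate interval with warning
  expect_warning(z <- prevalence_ci(0, 0), "zero events")
  expect_equal(unlist(z), c(ci_low = 0, ci_high = 0))
  # binomial alternative needs a denominator and stays in [0, 1]
  expect_error(prevalence_ci(0.01, 100, method = "binomial"), "persons")
  b <- prevalence_ci(0.01, 100, method = "binomial", persons = 1e5)
  expect_true(b$ci_low > 0 && b$ci_high < 1 && b$ci_low < 0.01)
})

test_that("rebinning onto coarse bands is the unweighted constituent mean", {
  t1 <- hes_table1()
  # identity on a coarse band with a single constituent
  single <- rebin_prevalence(t1[t1$age_band %in% c("85-89", "Above 90"), ],
                             fine = list(age_band(85, 89), age_band(90, Inf)),
                             coarse = list(age_band(85, 89),
                                           age_band(90, Inf)))
  expect_equal(single$point, t1$point[t1$age_band %in% c("85-89", "Above 90")])

  coarse <- rebin_prevalence(t1)
  expect_equal(coarse$age_band, band_labels(coarse_bands()))
  expect_equal(coarse$point[coarse$age_band == "50-59"],
               mean(c(0.00425, 0.00415)))
  expect_equal(coarse$point[coarse$age_band == "> 79"],
               mean(c(0.00205, 0.0012, 0.000365)))

  # a coarse band that no union of fine bands tiles is an error
  expect_error(rebin_prevalence(t1, coarse = list(age_band(0, 52),
                                                  age_band(53, Inf))),
               "union of whole fine bands")
})

test_that("rebin and band means commute with scalar rescaling", {
  t1 <- hes_table1()
  doubled <- t1
  doubled$point <- 2 * doubled$point
  doubled$ci_low <- 2 * doubled$ci_low
  doubled$ci_high <- 2 * doubled$ci_high
  expect_equal(rebin_prevalence(doubled)$point, 2 * rebin_prevalence(t1)$point)
  expect_equal(mean_over_bands(doubled)$mean, 2 * mean_over_bands(t1)$mean)
  same <- mean_over_bands(rep(0.004, 6))
  expect_equal(same$mean, 0.004)
  expect_equal(same$sd, 0)
})

test_that("the fitted model recovers a hand-computed two-band example", {
  # brute-force oracle: rates, duration and P = I*D computed longhand
  tt <- tiny_tables()
  sched <- const_schedule(0.02, width = 1)
  fit <- dcm_prevalence(tt$counts, tt$population, sched, smr = 1.18,
                        bands = tiny_bands())
  lt <- apply_smr(sched, 1.18)
  for (i in seq_along(tiny_bands())) {
    lb <- band_labels(tiny_bands())[i]
    rows <- tt$counts[tt$counts$age_band == lb, ]
    rate <- mean(rows$count / 1e6 * 1e5)
    dur <- life_expectancy_at(lt, band_midpoint(tiny_bands()[[i]]))
    expect_equal(unname(coef(fit)[lb]), rate / 1e5 * dur)
    expect_equal(fit$prevalence$total_events[fit$prevalence$age_band == lb],
                 sum(rows$count))
  }
  expect_s3_class(summary(fit), "summary.dcm_prevalence")
  expect_output(print(fit), "P = I \\* D")
  df <- as.data.frame(fit)
  expect_true(all(c("mean_rate", "duration", "point") %in% names(df)))
})
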
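# Rate multiplier for a care setting; the truth's incidence curve is the
# FCE-level rate.
#' @keywords internal
setting_multiplier <- function(truth, setting) {
  switch(match.arg(setting, c("fce", "admission", "outpatient")),
         fce = 1,
         admission = 1 / truth$fce_inflation,
         outpatient = truth$outpatient_fraction)
}

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Ground truth for a synthetic hospital registry
#'
#' Defines the data-generating process that stands in for a national
#' hospital-activity extract, with every quantity the pipeline estimates
#' known exactly:
#' \itemize{
#'   \item a log-quadratic age-incidence curve,
#'     `rate(a) = peak_rate * exp(-((a - peak_age) / width)^2)` per
#'     100,000 person-years, peaking in late old age as degenerative
#'     cervical myelopathy admissions do;
#'   \item a smooth population pyramid,
#'     `persons(a) = base_persons * plogis((pyramid_edge - a) /
#'     pyramid_scale)` per 5-year band, growing by `growth` per year —
#'     loosely England-like (about 3.5 million per young band, tapering
#'     in old age);
#'   \item a Gompertz-Makeham mortality law
#'     `mx(a) = makeham_a + gompertz_b * exp(theta * a)`;
#'   \item the true standardised mortality ratio of the disease.
#' }
#'
#' @param peak_age Age of peak incidence (years); default 77, the midpoint
#'   of the 75-79 band.
#' @param peak_rate Peak incidence per 100,000 person-years; default 27.9.
#' @param width Width of the log-quadratic peak (years); default 18.
#' @param base_persons,pyramid_edge,pyramid_scale Pyramid parameters
#'   (persons per band; years; years).
#' @param growth Annual population growth factor; default 0.005.
#' @param makeham_a Age-independent hazard per year; default 5e-4.
#' @param gompertz_b Gompertz level per year; default 2.5e-5.
#' @param theta Gompertz slope per year of age; default 0.1.
#' @param smr_true True standardised mortality ratio; default 1.18.
#' @param base_year Survey year at which the pyramid equals its base size.
#' @param fce_inflation Ratio of consultant episodes to admissions (one
#'   admission can span several episodes); default 1.23, the ratio of the
#'   national totals (35,078 episodes to 28,517 admissions). The incidence
#'   curve is defined on the `"fce"` setting; `"admission"` counts are
#'   simulated at `rate / fce_inflation`.
#' @param outpatient_fraction Outpatient attendance rate as a fraction of
#'   the FCE rate; default 0.105 (an all-ages outpatient rate of 1.19
#'   against an inpatient 11.3 per 100,000/year).
#' @param overdispersion Variance inflation for counts; 1 (default) gives
#'   Poisson, > 1 a negative binomial with the same mean.
#' @param seed Integer RNG seed.
#' @return List of class `registry_truth`; its `rate(age)` element returns
#'   the true incidence per person-year, `persons(age, year)` the pyramid.
#' @seealso [simulate_registry()], [truth_report()]
#' @export
registry_truth <- function(peak_age = 77, peak_rate = 27.9, width = 18,
                           base_persons = 3.6e6, pyramid_edge = 85,
                           pyramid_scale = 10, growth = 0.005,
                           makeham_a = 5e-4, gompertz_b = 2.5e-5,
                           theta = 0.1, smr_true = 1.18,
                           base_year = 2012, fce_inflation = 1.23,
                           outpatient_fraction = 0.105,
                           overdispersion = 1, seed = 1L) {
  if (peak_rate <= 0) stop("peak_rate must be positive")
  if (width <= 0) stop("width must be positive")
  if (makeham_a < 0 || gompertz_b < 0)
    stop("hazard parameters must be non-negative")
  if (smr_true <= 0) stop("smr_true must be positive")
  if (overdispersion < 1) stop("overdispersion must be >= 1")
  truth <- list(peak_age = peak_age, peak_rate = peak_rate, width = width,
                base_persons = base_persons, pyramid_edge = pyramid_edge,
                pyramid_scale = pyramid_scale, growth = growth,
                makeham_a = makeham_a, gompertz_b = gompertz_b,
                theta = theta, smr_true = smr_true, base_year = base_year,
                fce_inflation = fce_inflation,
                outpatient_fraction = outpatient_fraction,
                overdispersion = overdispersion, seed = as.integer(seed))
  truth$rate <- function(age)
    peak_rate / 1e5 * exp(-((age - peak_age) / width)^2)
  truth$persons <- function(age, year = base_year)
    base_persons * stats::plogis((pyramid_edge - age) / pyramid_scale) *
      (1 + growth)^(year - base_year)
  class(truth) <- "registry_truth"
  truth
}

#' @export
print.registry_truth <- function(x, ...) {
  cat("Synthetic registry truth: peak ", x$peak_rate,
      "/100,000/yr at age ", x$peak_age, " (width ", x$width,
      "), SMR ", x$smr_true, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Simulate annual case counts
#'
#' Draws one count per (year, band) cell with mean
#' `lambda = rate(band midpoint) * persons(band, year)`; Poisson by
#' default, negative binomial with the same mean when the truth's
#' `overdispersion` exceeds 1. The incidence curve is defined on the
#' `"fce"` setting; `"admission"` cells use `rate / fce_inflation` and
#' `"outpatient"` cells `rate * outpatient_fraction` (see
#' [registry_truth()]). Reproducible: the same truth (including seed)
#' always yields the same table, and the caller's RNG state is left
#' untouched.
#'
#' @param truth A [registry_truth()].
#' @param years Integer survey years.
#' @param bands Band scheme; default [fine_bands()].
#' @param setting Care-setting tag for the output table.
#' @return A counts data frame in the [read_counts()] schema.
#' @export
simulate_counts <- function(truth, years = 2012:2018, bands = fine_bands(),
                            setting = c("fce", "admission", "outpatient")) {
  stopifnot(inherits(truth, "registry_truth"), length(years) >= 1L)
  setting <- match.arg(setting)
  infl <- setting_multiplier(truth, setting)
  grid <- expand.grid(year = as.integer(years), age_band = band_labels(bands),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mids <- vapply(bands, band_midpoint, numeric(1))
  grid$lambda <- truth$rate(mids[match(grid$age_band, band_labels(bands))]) *
    infl *
    truth$persons(mids[match(grid$age_band, band_labels(bands))], grid$year)
  grid$count <- with_seed(truth$seed, {
    if (truth$overdispersion > 1) {
      size <- grid$lambda / (truth$overdispersion - 1)
      as.integer(stats::rnbinom(nrow(grid), mu = grid$lambda, size = size))
    } else as.integer(stats::rpois(nrow(grid), grid$lambda))
  })
  out <- grid[order(grid$year, match(grid$age_band, band_labels(bands))),
              c("year", "age_band", "count")]
  rownames(out) <- NULL
  attr(out, "setting") <- setting
  out
}

#' Deterministic population table for a synthetic registry
#'
#' @inheritParams simulate_counts
#' @return A population data frame in the [read_population()] schema
#'   (persons rounded to whole people).
#' @export
simulate_population <- function(truth, years = 2012:2018,
                                bands = fine_bands()) {
  stopifnot(inherits(truth, "registry_truth"))
  grid <- expand.grid(year = as.integer(years), age_band = band_labels(bands),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mids <- vapply(bands, band_midpoint, numeric(1))
  grid$persons <- round(truth$persons(
    mids[match(grid$age_band, band_labels(bands))], grid$year))
  out <- grid[order(grid$year, match(grid$age_band, band_labels(bands))), ]
  rownames(out) <- NULL
  out
}

#' Simulate a national mortality schedule
#'
#' Single-year Gompertz-Makeham central death rates
#' `mx(x) = A + B * exp(theta * x)` from age 0 up to an open terminal
#' interval at `max_age`.
#'
#' @param truth A [registry_truth()].
#' @param max_age Terminal interval start; default 100.
#' @return A `mortality_schedule` data frame (`age`, `n`, `mx`).
#' @export
simulate_life_table <- function(truth, max_age = 100) {
  stopifnot(inherits(truth, "registry_truth"), max_age >= 1)
  age <- 0:max_age
  mx <- truth$makeham_a + truth$gompertz_b * exp(truth$theta * age)
  if (all(mx == 0))
    stop("degenerate mortality law: all hazards zero")
  structure(data.frame(age = age, n = c(rep(1, max_age), Inf), mx = mx),
            class = c("mortality_schedule", "data.frame"))
}

#' True incidence and prevalence per band
#'
#' Evaluates the generator's own quantities through the same definitions
#' the pipeline estimates: incidence at the band midpoint, and prevalence
#' as `rate * SMR-adjusted life expectancy` at that midpoint. Generator
#' and estimator thereby share one definition of truth, so
#' parameter-recovery tests compare like with like.
#'
#' @param truth A [registry_truth()].
#' @param bands Band scheme; default [fine_bands()].
#' @param max_age Passed to [simulate_life_table()].
#' @param setting Care setting whose rates to report (same multipliers as
#'   [simulate_counts()]).
#' @return Data frame `age_band`, `midpoint_age`, `true_rate` (per
#'   100,000 person-years), `true_duration` (years), `true_prevalence`
#'   (proportion).
#' @export
truth_report <- function(truth, bands = fine_bands(), max_age = 100,
                         setting = "fce") {
  stopifnot(inherits(truth, "registry_truth"))
  lt <- apply_smr(simulate_life_table(truth, max_age), truth$smr_true)
  mids <- vapply(bands, band_midpoint, numeric(1))
  dur <- life_expectancy_at(lt, pmin(mids, max_age))
  rate <- truth$rate(mids) * 1e5 * setting_multiplier(truth, setting)
  data.frame(age_band = band_labels(bands), midpoint_age = mids,
             true_rate = rate, true_duration = dur,
             true_prevalence = extrapolate_prevalence(rate, dur),
             stringsAsFactors = FALSE)
}

#' Simulate a complete registry input bundle
#'
#' One call producing everything [dcm_prevalence()] consumes — counts,
#' population denominators and a mortality schedule — plus the truth
#' report for parameter-recovery checks.
#'
#' @inheritParams simulate_counts
#' @param max_age Terminal age of the simulated mortality schedule.
#' @return List of class `registry_sim` with elements `counts`,
#'   `population`, `life_table`, `truth_report`, `truth`, `years`,
#'   `bands`.
#' @examples
#' sim <- simulate_registry(registry_truth(seed = 42))
#' head(sim$counts)
#' @export
simulate_registry <- function(truth = registry_truth(), years = 2012:2018,
                              bands = fine_bands(),
                              setting = "fce", max_age = 100) {
  structure(list(counts = simulate_counts(truth, years, bands, setting),
                 population = simulate_population(truth, years, bands),
                 life_table = simulate_life_table(truth, max_age),
                 truth_report = truth_report(truth, bands, max_age, setting),
                 truth = truth, years = as.integer(years), bands = bands),
            class = "registry_sim")
}

#' @export
print.registry_sim <- function(x, ...) {
  cat("Synthetic registry bundle: ", length(x$years), " years x ",
      length(x$bands), " bands, ", sum(x$counts$count), " events\n",
      sep = "")
  print(x$truth)
  invisible(x)
}
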
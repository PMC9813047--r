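#' Prevalence from incidence and duration
#'
#' The steady-state relation P = I * D: prevalence as the product of the
#' incidence rate and the mean duration of disease. For an incurable
#' condition, duration is remaining life expectancy at the age of onset.
#'
#' @param incidence Incidence rate per 100,000 person-years (>= 0).
#' @param duration Mean disease duration in years (>= 0).
#' @return Prevalence as a proportion of the population,
#'   `incidence / 1e5 * duration`, capped at 1 with a warning should the
#'   product exceed it. Vectorised.
#' @examples
#' extrapolate_prevalence(27.9, 10.0)   # 0.00279, i.e. 0.279%
#' @export
extrapolate_prevalence <- function(incidence, duration) {
  if (any(incidence < 0)) stop("incidence must be non-negative")
  if (any(duration < 0)) stop("duration must be non-negative")
  p <- incidence / 1e5 * duration
  if (any(p > 1)) {
    warning("P = I*D exceeds 1 for ", sum(p > 1),
            " band(s); capping at 1")
    p <- pmin(p, 1)
  }
  p
}

#' Confidence interval for an extrapolated prevalence
#'
#' Prevalence inherits its sampling uncertainty from the observed event
#' count through the linear map P = I * D. The default (`"poisson"`)
#' interval is the normal-approximation Poisson interval on the count,
#' propagated in relative terms:
#' `point * (1 +/- z / sqrt(total_events))`, floored at 0. The
#' `"binomial"` alternative is a Wald interval on the proportion itself,
#' `point +/- z * sqrt(point * (1 - point) / persons)`, and requires the
#' population denominator.
#'
#' @param point Prevalence proportion(s).
#' @param total_events Event count(s) behind the estimate. Zero events
#'   yield the degenerate interval (0, point) with a warning.
#' @param method `"poisson"` (default) or `"binomial"`.
#' @param persons Population denominator, required for `"binomial"`.
#' @param conf_level Coverage, default 0.95.
#' @return A data frame with columns `ci_low`, `ci_high`.
#' @examples
#' prevalence_ci(0.01, 100)   # 0.00804 to 0.01196
#' @export
prevalence_ci <- function(point, total_events,
                          method = c("poisson", "binomial"),
                          persons = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  if (any(total_events < 0)) stop("total_events must be non-negative")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "poisson") {
    rel <- ifelse(total_events > 0, z / sqrt(total_events), NA_real_)
    lo <- ifelse(total_events > 0, pmax(0, point * (1 - rel)), 0)
    hi <- ifelse(total_events > 0, point * (1 + rel), point)
    if (any(total_events == 0))
      warning("zero events: returning degenerate interval (0, point)")
  } else {
    if (is.null(persons)) stop("binomial interval needs a persons denominator")
    se <- sqrt(point * (1 - point) / persons)
    lo <- pmax(0, point - z * se)
    hi <- pmin(1, point + z * se)
  }
  data.frame(ci_low = lo, ci_high = hi)
}

#' Construct a prevalence-points table
#'
#' The common currency of the comparison stages: one prevalence estimate
#' per age band, as proportions, with interval bounds and a source tag.
#'
#' @param bands Band scheme (list of [age_band()]) or character labels.
#' @param point,ci_low,ci_high Proportions, one per band.
#' @param source One of `"hospital"`, `"scc_pooled"`, `"scc_lower"`,
#'   `"scc_upper"`.
#' @param total_events Optional integer events per band (hospital source).
#' @return Data frame of class `prevalence_points` with columns
#'   `age_band`, `point`, `ci_low`, `ci_high`, `source`, `total_events`.
#' @export
prevalence_points <- function(bands, point, ci_low = NA_real_,
                              ci_high = NA_real_,
                              source = c("hospital", "scc_pooled",
                                         "scc_lower", "scc_upper"),
                              total_events = NA_integer_) {
  source <- match.arg(source)
  labels <- if (is.character(bands)) bands else band_labels(bands)
  stopifnot(length(point) == length(labels))
  ok <- !is.na(ci_low) & !is.na(ci_high)
  if (any(point[!is.na(point)] < 0 | point[!is.na(point)] > 1))
    stop("prevalence points must be proportions in [0, 1]")
  if (any(ok & (ci_low > point | ci_high < point)))
    stop("interval bounds must bracket the point estimate")
  structure(data.frame(age_band = labels, point = point,
                       ci_low = ci_low, ci_high = ci_high,
                       source = source, total_events = total_events,
                       stringsAsFactors = FALSE),
            class = c("prevalence_points", "data.frame"))
}

#' Reformat fine-band estimates onto a coarse scheme
#'
#' Each coarse band must be a union of whole fine bands; its point and
#' interval bounds are the unweighted arithmetic mean of the constituent
#' fine-band values, and constituent event counts are summed. The
#' unweighted mean (rather than a population-weighted one) is the
#' reformatting rule used when standardised age groups are built directly
#' from stratum-level estimates.
#'
#' @param points A `prevalence_points` table on the fine scheme.
#' @param fine,coarse Band schemes; defaults [fine_bands()],
#'   [coarse_bands()].
#' @return A `prevalence_points` table on the coarse scheme.
#' @export
rebin_prevalence <- function(points, fine = fine_bands(),
                             coarse = coarse_bands()) {
  idx <- match_bands(points$age_band, fine)
  out <- lapply(coarse, function(cb) {
    members <- vapply(fine, function(fb) {
      fb$lower >= cb$lower &&
        (if (cb$open) TRUE else !fb$open && fb$upper <= cb$upper)
    }, logical(1))
    # a coarse band must be exactly tiled by whole fine bands
    covered <- sum(vapply(fine[members], function(fb) {
      if (fb$open) Inf else fb$upper - fb$lower + 1
    }, numeric(1)))
    span <- if (cb$open) Inf else as.numeric(cb$upper - cb$lower + 1)
    if (!any(members) || covered != span)
      stop("coarse band '", cb$label,
           "' is not a union of whole fine bands")
    rows <- points[idx %in% which(members), , drop = FALSE]
    if (nrow(rows) != sum(members))
      stop("fine estimates missing for coarse band '", cb$label, "'")
    data.frame(age_band = cb$label, point = mean(rows$point),
               ci_low = mean(rows$ci_low), ci_high = mean(rows$ci_high),
               source = rows$source[1],
               total_events = if (all(is.na(rows$total_events))) NA_integer_
                              else sum(rows$total_events, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("prevalence_points", "data.frame")
  out
}

#' Unweighted summary across age bands
#'
#' @param points A `prevalence_points` table (or numeric vector of
#'   proportions).
#' @return List with `mean` and `sd` (sample SD) over band points.
#' @export
mean_over_bands <- function(points) {
  v <- if (is.data.frame(points)) points$point else points
  if (!length(v)) stop("mean_over_bands: no estimates")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
}

#' Fit the hospital-registry prevalence model
#'
#' The central estimator of the package. From annual case counts,
#' population denominators and a national mortality schedule it computes,
#' per age band:
#' \enumerate{
#'   \item incidence I as the mean over survey years of the yearly rate
#'     per 100,000 person-years ([estimate_incidence()]);
#'   \item duration D as remaining life expectancy at the band midpoint,
#'     from the mortality schedule inflated by the disease's standardised
#'     mortality ratio ([apply_smr()], [duration_at()]);
#'   \item prevalence P = I * D as a proportion
#'     ([extrapolate_prevalence()]), with a confidence interval driven by
#'     the band's total event count ([prevalence_ci()]).
#' }
#'
#' @param counts Case-count table (schema of [read_counts()]).
#' @param population Denominator table (schema of [read_population()]).
#' @param life_table Mortality schedule (columns `age`, `mx`), e.g. from
#'   [read_life_table()] or [simulate_life_table()].
#' @param smr Standardised mortality ratio of the disease; 1.18 for DCM.
#' @param bands Band scheme; default [fine_bands()].
#' @param ci_method `"poisson"` (default) or `"binomial"`; see
#'   [prevalence_ci()].
#' @param conf_level Interval coverage, default 0.95.
#' @return An object of class `dcm_prevalence`: a list with components
#'   `prevalence` (a `prevalence_points` table), `incidence` (an
#'   `incidence_estimate`), `duration` (years per band), `life_table`
#'   (SMR-adjusted), `life_table_unadjusted`, `smr`, `bands`, `ci_method`,
#'   `conf_level` and `call`. Supports `print()`, `summary()`, `coef()`
#'   (band prevalences as proportions), `as.data.frame()` and `plot()`.
#' @examples
#' truth <- registry_truth(seed = 1)
#' sim <- simulate_registry(truth)
#' fit <- dcm_prevalence(sim$counts, sim$population, sim$life_table)
#' fit
#' coef(fit)[["75-79"]]
#' @export
dcm_prevalence <- function(counts, population, life_table, smr = 1.18,
                           bands = fine_bands(),
                           ci_method = c("poisson", "binomial"),
                           conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  bands <- validate_band_scheme(bands)
  inc <- estimate_incidence(counts, population, bands = bands)
  lt0 <- build_life_table(life_table)
  lt <- apply_smr(life_table, smr)
  keep <- bands[match(inc$age_band, band_labels(bands))]
  dur <- vapply(keep, function(b) duration_at(lt, b), numeric(1))
  point <- extrapolate_prevalence(inc$mean_rate, dur)
  per_year <- attr(inc, "per_year")
  persons <- vapply(inc$age_band, function(lb)
    mean(per_year$persons[per_year$age_band == lb]), numeric(1))
  ci <- prevalence_ci(point, inc$total_events, method = ci_method,
                      persons = persons, conf_level = conf_level)
  prev <- prevalence_points(inc$age_band, point, ci$ci_low, ci$ci_high,
                            source = "hospital",
                            total_events = inc$total_events)
  structure(list(prevalence = prev, incidence = inc, duration = dur,
                 life_table = lt, life_table_unadjusted = lt0, smr = smr,
                 bands = keep, ci_method = ci_method,
                 conf_level = conf_level, call = match.call()),
            class = "dcm_prevalence")
}

#' @export
coef.dcm_prevalence <- function(object, ...) {
  stats::setNames(object$prevalence$point, object$prevalence$age_band)
}

#' @export
as.data.frame.dcm_prevalence <- function(x, ...) {
  data.frame(age_band = x$prevalence$age_band,
             mean_rate = x$incidence$mean_rate,
             sd_rate = x$incidence$sd_rate,
             total_events = x$incidence$total_events,
             duration = x$duration,
             point = x$prevalence$point,
             ci_low = x$prevalence$ci_low,
             ci_high = x$prevalence$ci_high,
             stringsAsFactors = FALSE)
}

#' @export
print.dcm_prevalence <- function(x, digits = 3, ...) {
  p <- x$prevalence
  peak <- which.max(p$point)
  cat("Hospital-registry prevalence model (P = I * D)\n")
  cat("  bands: ", nrow(p), "; years per band: ",
      x$incidence$n_years[1], "; SMR: ", x$smr,
      "; CI: ", x$ci_method, "\n", sep = "")
  cat("  total events: ", sum(x$incidence$total_events), "\n", sep = "")
  cat("  peak prevalence: ", format(100 * p$point[peak], digits = digits),
      "% at ", p$age_band[peak], "\n", sep = "")
  m <- mean_over_bands(p)
  cat("  mean prevalence across bands: ",
      format(100 * m$mean, digits = digits), "% (sd ",
      format(100 * m$sd, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.dcm_prevalence <- function(object, ...) {
  out <- as.data.frame(object)
  structure(list(table = out, smr = object$smr,
                 mean = mean_over_bands(object$prevalence),
                 call = object$call),
            class = "summary.dcm_prevalence")
}

#' @export
print.summary.dcm_prevalence <- function(x, digits = 3, ...) {
  cat("Call: ", deparse(x$call), "\n\n")
  tab <- x$table
  tab$point <- 100 * tab$point
  tab$ci_low <- 100 * tab$ci_low
  tab$ci_high <- 100 * tab$ci_high
  names(tab)[names(tab) %in% c("point", "ci_low", "ci_high")] <-
    c("prevalence_pct", "ci_low_pct", "ci_high_pct")
  print(tab, digits = digits, row.names = FALSE)
  cat("\nMean prevalence across bands: ",
      format(100 * x$mean$mean, digits = digits), "% (sd ",
      format(100 * x$mean$sd, digits = digits), "), SMR ", x$smr, "\n",
      sep = "")
  invisible(x)
}

#' Plot a fitted prevalence model
#'
#' Draws the age profile of the fit: band-wise prevalence with its
#' confidence band, or incidence, on the band midpoints.
#'
#' @param x A `dcm_prevalence` fit.
#' @param which `"prevalence"` (default) or `"incidence"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dcm_prevalence <- function(x, which = c("prevalence", "incidence"),
                                ...) {
  which <- match.arg(which)
  mids <- vapply(x$bands, band_midpoint, numeric(1))
  if (which == "prevalence") {
    p <- x$prevalence
    graphics::plot(mids, 100 * p$point, type = "b", pch = 16,
                   xlab = "Age (band midpoint, years)",
                   ylab = "Prevalence (% of population)",
                   ylim = range(0, 100 * p$ci_high, na.rm = TRUE), ...)
    graphics::arrows(mids, 100 * p$ci_low, mids, 100 * p$ci_high,
                     angle = 90, code = 3, length = 0.03)
  } else {
    graphics::plot(mids, x$incidence$mean_rate, type = "b", pch = 16,
                   xlab = "Age (band midpoint, years)",
                   ylab = "Incidence (per 100,000 person-years)", ...)
  }
  invisible(x)
}
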
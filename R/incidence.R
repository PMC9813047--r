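#' Annual incidence rate per 100,000 person-years
#'
#' @param count Event count (non-negative).
#' @param persons Mid-year population at risk (positive).
#' @return `count / persons * 1e5`. Vectorised.
#' @examples
#' annual_rate(50, 200000)  # 25 per 100,000 person-years
#' @export
annual_rate <- function(count, persons) {
  if (any(persons <= 0)) stop("persons must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  count / persons * 1e5
}

#' Mean and spread of per-year values
#'
#' Survey-year summaries are presented as mean with sample standard
#' deviation (n - 1 denominator); with a single year the SD is undefined
#' and returned as `NA`.
#'
#' @param values Numeric vector, one value per survey year.
#' @return A list with `mean`, `sd` and `n_years`.
#' @export
summarise_years <- function(values) {
  if (!length(values)) stop("summarise_years: no values")
  list(mean = mean(values),
       sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
       n_years = length(values))
}

#' Age-stratified incidence from counts and denominators
#'
#' Computes the rate per (year, band) cell with [annual_rate()], then
#' summarises each band across survey years with equal weight: the
#' reported `mean_rate` is the arithmetic mean of the per-year rates, not
#' a pooled-count rate, matching the mean-and-SD presentation of annual
#' registry extracts.
#'
#' @param counts Counts table ([read_counts()] schema: `year`, `age_band`,
#'   `count`).
#' @param population Denominator table ([read_population()] schema).
#' @param bands Band scheme the labels belong to; defaults to
#'   [fine_bands()].
#' @return A data frame of class `incidence_estimate`, one row per band in
#'   scheme order: `age_band`, `mean_rate`, `sd_rate` (per 100,000
#'   person-years), `total_events`, `n_years`, plus the per-cell rates in
#'   attribute `"per_year"` (long data frame `year`, `age_band`, `rate`).
#' @examples
#' cnt <- data.frame(year = c(2012, 2013), age_band = "50-54",
#'                   count = c(40, 60))
#' pop <- data.frame(year = c(2012, 2013), age_band = "50-54",
#'                   persons = c(2e5, 2e5))
#' bands <- list(age_band(50, 54), age_band(55, Inf))
#' estimate_incidence(cnt, pop, bands = bands)
#' @export
estimate_incidence <- function(counts, population, bands = fine_bands()) {
  present <- intersect(band_labels(bands), unique(counts$age_band))
  if (!length(present)) stop("no count rows match the band scheme")
  match_bands(counts$age_band, bands)
  m <- merge(counts, population, by = c("year", "age_band"))
  if (nrow(m) < nrow(counts))
    stop("population denominators missing for some (year, age_band) cells")
  m$rate <- annual_rate(m$count, m$persons)
  m <- m[order(match(m$age_band, band_labels(bands)), m$year), ]
  rownames(m) <- NULL
  out <- do.call(rbind, lapply(present, function(lb) {
    rows <- m[m$age_band == lb, , drop = FALSE]
    s <- summarise_years(rows$rate)
    data.frame(age_band = lb, mean_rate = s$mean, sd_rate = s$sd,
               total_events = sum(rows$count), n_years = s$n_years,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "per_year") <- m[c("year", "age_band", "count", "persons", "rate")]
  attr(out, "setting") <- attr(counts, "setting")
  class(out) <- c("incidence_estimate", "data.frame")
  out
}

#' Total events in a counts table
#'
#' @param counts Counts table (`year`, `age_band`, `count`).
#' @return Integer sum over all years and bands.
#' @export
total_events <- function(counts) {
  if (!nrow(counts)) return(0L)
  sum(as.integer(counts$count))
}

#' Overall (all-ages) incidence rate
#'
#' Mean over survey years of the crude yearly rate: total events in a year
#' divided by total persons that year, per 100,000. Used for settings with
#' no age stratification (outpatient attendances) and for the all-ages
#' inpatient rate.
#'
#' @param counts Counts table; `age_band` may be a single "all ages" label.
#' @param population Denominator table covering the same years (summed over
#'   its bands within each year).
#' @return A list with `mean`, `sd`, `n_years` (rate per 100,000
#'   person-years).
#' @export
overall_rate <- function(counts, population) {
  ev <- tapply(counts$count, counts$year, sum)
  pp <- tapply(population$persons, population$year, sum)
  yrs <- names(ev)
  if (!all(yrs %in% names(pp)))
    stop("population years do not cover count years: missing ",
         paste(setdiff(yrs, names(pp)), collapse = ", "))
  summarise_years(annual_rate(as.numeric(ev), as.numeric(pp[yrs])))
}
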
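#' Conversion rate from pooled prevalences
#'
#' Radiological spinal cord compression (SCC) is necessary but not
#' sufficient for DCM, so the proportion of people with SCC who also have
#' DCM — the conversion rate — is the ratio of the pooled DCM prevalence to
#' the pooled SCC prevalence.
#'
#' @param dcm_pooled Pooled DCM prevalence (proportion).
#' @param scc_pooled Pooled SCC prevalence (proportion, > 0).
#' @return `dcm_pooled / scc_pooled`.
#' @examples
#' conversion_from_pooled(0.023, 0.244)
#' @export
conversion_from_pooled <- function(dcm_pooled, scc_pooled) {
  if (any(scc_pooled <= 0) || any(scc_pooled > 1))
    stop("scc_pooled must be in (0, 1]")
  if (any(dcm_pooled < 0)) stop("dcm_pooled must be non-negative")
  if (any(dcm_pooled > scc_pooled))
    stop("dcm_pooled exceeds scc_pooled: SCC is necessary for DCM")
  dcm_pooled / scc_pooled
}

#' Conversion-rate specification
#'
#' A pooled SCC-to-DCM conversion rate with the lower and upper bounds
#' reported across individual studies.
#'
#' @param pooled,lower,upper Proportions with
#'   `0 < lower <= pooled <= upper <= 1`.
#' @return List of class `conversion_rates`.
#' @export
conversion_rates <- function(pooled, lower, upper) {
  if (!(is.numeric(pooled) && is.numeric(lower) && is.numeric(upper)))
    stop("conversion rates must be numeric")
  if (!(lower > 0 && lower <= pooled && pooled <= upper && upper <= 1))
    stop("conversion rates must satisfy 0 < lower <= pooled <= upper <= 1")
  structure(list(pooled = pooled, lower = lower, upper = upper),
            class = "conversion_rates")
}

#' DCM prevalence extrapolated from an SCC prevalence curve
#'
#' Applies a single, age-constant conversion rate (and its bounds) to an
#' age-stratified SCC prevalence curve: per band, the pooled estimate is
#' `curve * pooled` and the bound estimates are `curve * lower` and
#' `curve * upper`. Consequently the bound-to-point ratios are the same
#' constant in every band — a structural property of the age-constant
#' conversion assumption.
#'
#' A warning (not an error) is raised if the curve decreases with age,
#' since degenerative compression prevalence is expected to rise.
#'
#' @param curve Named numeric vector: band label -> SCC prevalence
#'   (proportion in `[0, 1]`). Bands are the curve's native ones; use
#'   [rebin_prevalence()] afterwards to map onto a comparison scheme.
#' @param rates A [conversion_rates()] object.
#' @return A list of three `prevalence_points` tables: `pooled`, `lower`,
#'   `upper` (sources `scc_pooled`, `scc_lower`, `scc_upper`). Each
#'   `pooled` table carries its bound companions in `ci_low`/`ci_high` for
#'   convenience.
#' @examples
#' curve <- c("< 50" = 0.10, "50-59" = 0.15)
#' extrapolate_scc(curve, conversion_rates(0.2, 0.04, 0.24))
#' @export
extrapolate_scc <- function(curve, rates) {
  stopifnot(inherits(rates, "conversion_rates"))
  if (is.null(names(curve)) || any(!nzchar(names(curve))))
    stop("scc curve must be a named vector (band label -> proportion)")
  if (any(curve < 0 | curve > 1))
    stop("scc curve values must be proportions in [0, 1]")
  if (is.unsorted(curve))
    warning("SCC prevalence curve is not non-decreasing with age")
  lab <- names(curve)
  pooled <- prevalence_points(lab, curve * rates$pooled,
                              ci_low = curve * rates$lower,
                              ci_high = curve * rates$upper,
                              source = "scc_pooled")
  lower <- prevalence_points(lab, curve * rates$lower, source = "scc_lower")
  upper <- prevalence_points(lab, curve * rates$upper, source = "scc_upper")
  list(pooled = pooled, lower = lower, upper = upper)
}
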
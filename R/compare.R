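#' Compare hospital-derived and SCC-derived prevalence
#'
#' Joins the two estimates on a common (coarse) band scheme and reports,
#' per band, the mismatch ratio (SCC-derived point over hospital point)
#' and whether the hospital confidence interval intersects the
#' SCC-derived bound interval. Non-overlap marks bands where the two
#' estimation routes disagree beyond their stated uncertainty — the
#' diagnostic-gap signal.
#'
#' @param hospital A `prevalence_points` table (source `hospital`) with
#'   `ci_low`/`ci_high`.
#' @param scc A `prevalence_points` table (source `scc_pooled`) whose
#'   `ci_low`/`ci_high` hold the lower/upper conversion-rate bounds, as
#'   returned by [extrapolate_scc()]`$pooled` (after rebinning).
#' @return Data frame of class `prevalence_comparison`: `age_band`,
#'   `hospital`, `hospital_low`, `hospital_high`, `scc`, `scc_low`,
#'   `scc_high`, `mismatch_ratio`, `overlap` (all prevalences as
#'   proportions).
#' @examples
#' h <- prevalence_points("60-69", 0.0036, 0.00349, 0.00372)
#' s <- prevalence_points("60-69", 0.0209, 0.0041, 0.02524,
#'                        source = "scc_pooled")
#' compare_prevalence(h, s)
#' @export
compare_prevalence <- function(hospital, scc) {
  if (!identical(hospital$age_band, scc$age_band))
    stop("hospital and SCC estimates are on different band schemes: ",
         paste(hospital$age_band, collapse = ", "), " vs ",
         paste(scc$age_band, collapse = ", "))
  overlap <- pmax(hospital$ci_low, scc$ci_low) <=
    pmin(hospital$ci_high, scc$ci_high)
  out <- data.frame(age_band = hospital$age_band,
                    hospital = hospital$point,
                    hospital_low = hospital$ci_low,
                    hospital_high = hospital$ci_high,
                    scc = scc$point, scc_low = scc$ci_low,
                    scc_high = scc$ci_high,
                    mismatch_ratio = scc$point / hospital$point,
                    overlap = overlap, stringsAsFactors = FALSE)
  class(out) <- c("prevalence_comparison", "data.frame")
  out
}

#' Year of birth for a survey-year x age-band cell
#'
#' The band's midpoint age subtracted from the survey year, rounded to the
#' nearest integer. Open bands use their representative age (the lower
#' edge), as in the life-table convention.
#'
#' @param survey_year Integer survey year(s).
#' @param band An [age_band()].
#' @return Integer year(s) of birth.
#' @examples
#' birth_year(2012, age_band(50, 54))  # 1960
#' @export
birth_year <- function(survey_year, band) {
  as.integer(round(survey_year - band_midpoint(band)))
}

#' Long-format cohort table
#'
#' Reshapes per-year, per-band prevalence into the long table behind
#' age-period-cohort graphs: each cell carries its survey year, band,
#' midpoint age, year of birth and prevalence. The reshaping is lossless —
#' regrouping by (survey_year, age_band) recovers the input.
#'
#' @param prevalence Data frame with columns `year`, `age_band`,
#'   `prevalence` (proportions), one row per survey-year x band cell.
#' @param bands Band scheme the labels belong to.
#' @return Data frame of class `cohort_table`: `survey_year`, `age_band`,
#'   `midpoint_age`, `birth_year`, `prevalence`.
#' @export
cohort_table <- function(prevalence, bands = fine_bands()) {
  need <- c("year", "age_band", "prevalence")
  stopifnot(all(need %in% names(prevalence)))
  idx <- match_bands(prevalence$age_band, bands)
  mids <- vapply(bands, band_midpoint, numeric(1))[idx]
  out <- data.frame(survey_year = as.integer(prevalence$year),
                    age_band = prevalence$age_band,
                    midpoint_age = mids,
                    birth_year = as.integer(round(prevalence$year - mids)),
                    prevalence = prevalence$prevalence,
                    stringsAsFactors = FALSE)
  out <- out[order(out$survey_year, out$midpoint_age), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Within-age-group cohort slopes
#'
#' A descriptive diagnostic for a cohort (year-of-birth) effect: within
#' each age band, the least-squares slope of prevalence against year of
#' birth. With rates driven by age alone the slopes scatter around zero;
#' a birth-cohort effect shows up as systematically signed slopes. This is
#' a graphical-inspection aid, not an identified age-period-cohort
#' decomposition.
#'
#' @param cohort A [cohort_table()].
#' @return Data frame `age_band`, `slope` (prevalence per birth year),
#'   `n_cells`; bands with fewer than 2 cells get `NA`.
#' @export
cohort_slopes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  bands <- unique(cohort$age_band)
  out <- do.call(rbind, lapply(bands, function(lb) {
    rows <- cohort[cohort$age_band == lb, ]
    slope <- if (nrow(rows) >= 2 && stats::var(rows$birth_year) > 0)
      unname(stats::coef(stats::lm(prevalence ~ birth_year, rows))[2])
    else NA_real_
    data.frame(age_band = lb, slope = slope, n_cells = nrow(rows),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Outpatient-to-inpatient incidence ratio
#'
#' Contrast of the all-ages outpatient attendance rate with the inpatient
#' episode rate; a small ratio indicates that adding outpatient activity
#' cannot close a prevalence mismatch.
#'
#' @param outpatient_rate,inpatient_rate Rates per 100,000 person-years;
#'   the inpatient rate must be positive.
#' @return `outpatient_rate / inpatient_rate`.
#' @examples
#' outpatient_ratio(1.19, 11.3)
#' @export
outpatient_ratio <- function(outpatient_rate, inpatient_rate) {
  if (any(inpatient_rate <= 0)) stop("inpatient rate must be positive")
  if (any(outpatient_rate < 0)) stop("outpatient rate must be non-negative")
  outpatient_rate / inpatient_rate
}
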
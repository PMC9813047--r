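#' Age bands
#'
#' An age band is a labelled integer age interval, closed (`"50-54"`) or
#' open-ended above (`"Above 90"`, `"> 79"`) or below (`"< 50"`). Bands are
#' the universal stratification key of the package: case counts, population
#' denominators, incidence, duration and prevalence are all indexed by band.
#'
#' `age_band()` constructs a band directly; [parse_band_label()] builds one
#' from a printed label. A band scheme is simply a list of bands; see
#' [fine_bands()], [coarse_bands()] and [validate_band_scheme()].
#'
#' @param lower Integer lower age (years, inclusive).
#' @param upper Integer upper age (years, inclusive), or `Inf` for an
#'   open-ended terminal band.
#' @param label Display label; defaults to `"lower-upper"` or
#'   `"Above lower"`.
#' @return An object of class `age_band` with fields `lower`, `upper`
#'   (`Inf` when open), `open` and `label`.
#' @examples
#' age_band(50, 54)
#' age_band(90, Inf)
#' @export
age_band <- function(lower, upper, label = NULL) {
  stopifnot(is.numeric(lower), length(lower) == 1L, lower >= 0,
            is.numeric(upper), length(upper) == 1L)
  open <- is.infinite(upper)
  if (!open && upper < lower)
    stop("age_band: upper (", upper, ") below lower (", lower, ")")
  if (is.null(label))
    label <- if (open) paste("Above", lower) else paste0(lower, "-", upper)
  structure(list(lower = as.integer(lower),
                 upper = if (open) Inf else as.integer(upper),
                 open = open, label = label),
            class = "age_band")
}

#' @export
print.age_band <- function(x, ...) {
  cat("<age_band> ", x$label,
      if (x$open) sprintf(" [%d, Inf)", x$lower)
      else sprintf(" [%d, %d]", x$lower, x$upper), "\n", sep = "")
  invisible(x)
}

#' @export
format.age_band <- function(x, ...) x$label

#' Parse an age-band label
#'
#' Accepts the label styles found in published hospital-activity tables:
#' `"L-U"` (any of hyphen, en dash, em dash, minus sign, optionally spaced),
#' `"Above L"` (ages L and over), `"> L"` (strictly over L, i.e. ages L+1
#' and over) and `"< U"` (strictly under U, i.e. ages 0 to U-1). The
#' original label is preserved verbatim on the returned band.
#'
#' @param label Character scalar.
#' @return An [age_band()].
#' @examples
#' parse_band_label("0–4")     # en dash, as printed
#' parse_band_label("Above 90")
#' parse_band_label("> 79")
#' @export
parse_band_label <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  raw <- label
  # normalise unicode dash variants to a plain hyphen, collapse whitespace
  x <- gsub("[‐‒–—―−]", "-", label)
  x <- gsub("\\s+", " ", trimws(x))
  if (grepl("^[0-9]+ ?- ?[0-9]+$", x)) {
    parts <- as.integer(strsplit(x, " ?- ?")[[1]])
    return(age_band(parts[1], parts[2], label = raw))
  }
  if (grepl("^[Aa]bove ?[0-9]+$", x)) {
    lo <- as.integer(sub("^[Aa]bove ?", "", x))
    return(age_band(lo, Inf, label = raw))
  }
  if (grepl("^> ?[0-9]+$", x)) {
    lo <- as.integer(sub("^> ?", "", x))
    return(age_band(lo + 1L, Inf, label = raw))
  }
  if (grepl("^< ?[0-9]+$", x)) {
    up <- as.integer(sub("^< ?", "", x))
    if (up < 1L) stop("parse_band_label: empty band '", raw, "'")
    return(age_band(0L, up - 1L, label = raw))
  }
  stop("parse_band_label: cannot parse age-band label '", raw, "'")
}

#' Representative (midpoint) age of a band
#'
#' Closed bands use the arithmetic midpoint, e.g. 52 for 50-54. Open bands
#' use their lower edge (90 for "Above 90"): the least-assumption anchor,
#' since the age distribution inside an open band is unknown.
#'
#' @param band An [age_band()].
#' @return Numeric age in years.
#' @export
band_midpoint <- function(band) {
  stopifnot(inherits(band, "age_band"))
  if (band$open) band$lower else (band$lower + band$upper) / 2
}

#' Standard band schemes
#'
#' `fine_bands()` returns the 19 five-year strata `0-4` ... `85-89`,
#' `Above 90` used for the hospital-registry analysis. `coarse_bands()`
#' returns the standardised comparison scheme `< 50`, `50-59`, `60-69`,
#' `70-79`, `> 79` onto which both prevalence estimates are reformatted.
#'
#' @return A list of [age_band()] objects covering ages 0 to infinity.
#' @export
fine_bands <- function() {
  lows <- seq(0L, 85L, by = 5L)
  c(lapply(lows, function(l) age_band(l, l + 4L)),
    list(age_band(90L, Inf, label = "Above 90")))
}

#' @rdname fine_bands
#' @export
coarse_bands <- function() {
  list(age_band(0L, 49L, label = "< 50"),
       age_band(50L, 59L),
       age_band(60L, 69L),
       age_band(70L, 79L),
       age_band(80L, Inf, label = "> 79"))
}

#' Validate a band scheme
#'
#' Checks that a list of bands covers ages 0 to infinity with pairwise
#' disjoint, contiguous intervals and exactly one open terminal band.
#'
#' @param bands List of [age_band()] objects.
#' @return The scheme, invisibly, sorted by lower age; errors on gaps,
#'   overlaps, or a missing/duplicated terminal band.
#' @export
validate_band_scheme <- function(bands) {
  stopifnot(is.list(bands), length(bands) >= 1L,
            all(vapply(bands, inherits, logical(1), "age_band")))
  ord <- order(vapply(bands, function(b) b$lower, numeric(1)))
  bands <- bands[ord]
  n <- length(bands)
  if (sum(vapply(bands, function(b) b$open, logical(1))) != 1L ||
      !bands[[n]]$open)
    stop("band scheme must end in exactly one open terminal band")
  if (bands[[1]]$lower != 0L)
    stop("band scheme must start at age 0, starts at ", bands[[1]]$lower)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      expected <- bands[[i]]$upper + 1
      got <- bands[[i + 1L]]$lower
      if (got > expected)
        stop("gap in band scheme between age ", bands[[i]]$upper,
             " and ", got)
      if (got < expected)
        stop("overlap in band scheme at age ", got)
    }
  }
  invisible(bands)
}

#' @keywords internal
band_labels <- function(bands) vapply(bands, function(b) b$label, character(1))

# Match character labels to a scheme's bands; errors on unknown labels.
#' @keywords internal
match_bands <- function(labels, bands) {
  idx <- match(labels, band_labels(bands))
  if (anyNA(idx))
    stop("unknown age-band label(s): ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}
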
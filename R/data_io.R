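#' Read an annual case-count table
#'
#' Counts of hospital events per survey year and age band, one care setting
#' per file. Survey years are fiscal years labelled by their start (2012
#' stands for 2012-13). The expected CSV schema is a header row and columns
#' `year`, `age_band`, `count`.
#'
#' When `years` and `bands` are supplied the table is checked for
#' completeness over the full `years x bands` grid; missing cells are an
#' error unless `fill_missing = "zero"`, which inserts zero counts (the
#' convention for small-count suppression in public extracts).
#'
#' @param path CSV file path.
#' @param setting Care setting tag: `"fce"` (finished consultant episodes),
#'   `"admission"` or `"outpatient"`.
#' @param years Optional integer vector of survey years the table must cover.
#' @param bands Optional band scheme (list of [age_band()]) the table must
#'   cover.
#' @param fill_missing `"error"` (default) or `"zero"`.
#' @return A `data.frame` with columns `year` (integer), `age_band`
#'   (character label) and `count` (integer), carrying the setting in
#'   attribute `"setting"`.
#' @seealso [write_counts()], [read_population()], [simulate_counts()]
#' @export
read_counts <- function(path, setting = c("fce", "admission", "outpatient"),
                        years = NULL, bands = NULL,
                        fill_missing = c("error", "zero")) {
  setting <- match.arg(setting)
  fill_missing <- match.arg(fill_missing)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("year", "age_band", "count")
  if (!all(need %in% names(df)))
    stop("counts file ", path, " must have columns ",
         paste(need, collapse = ", "))
  df <- df[need]
  df$year <- as.integer(df$year)
  df$age_band <- as.character(df$age_band)
  df$count <- as.integer(df$count)
  if (anyNA(df)) stop("counts file ", path, " contains missing values")
  if (any(df$count < 0)) stop("negative counts in ", path)
  key <- paste(df$year, df$age_band, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (year, age_band) keys in ", path, ": ",
         paste(unique(df$age_band[duplicated(key)]), collapse = ", "))
  if (!is.null(bands)) match_bands(df$age_band, bands)  # validates labels
  if (!is.null(years) && !is.null(bands)) {
    grid <- expand.grid(year = as.integer(years), age_band = band_labels(bands),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    gkey <- paste(grid$year, grid$age_band, sep = "\r")
    miss <- setdiff(gkey, key)
    if (length(miss)) {
      if (fill_missing == "error")
        stop(length(miss), " missing (year, age_band) cells in ", path,
             "; first: ", gsub("\r", " / ", miss[1]))
      add <- grid[gkey %in% miss, , drop = FALSE]
      add$count <- 0L
      df <- rbind(df, add)
    }
    extra <- setdiff(key, gkey)
    if (length(extra))
      stop("cells outside declared years x bands in ", path,
           "; first: ", gsub("\r", " / ", extra[1]))
  }
  df <- df[order(df$year, match(df$age_band, unique(df$age_band))), ]
  rownames(df) <- NULL
  attr(df, "setting") <- setting
  df
}

#' Write an annual case-count table
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f), ...)`
#' reproduces `x` exactly.
#'
#' @param counts Data frame with columns `year`, `age_band`, `count`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  stopifnot(all(c("year", "age_band", "count") %in% names(counts)))
  utils::write.csv(counts[c("year", "age_band", "count")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a population-denominator table
#'
#' Persons per survey year and age band. CSV schema: header row, columns
#' `year`, `age_band`, `persons`; all persons must be positive.
#'
#' @inheritParams read_counts
#' @return A `data.frame` with columns `year`, `age_band`, `persons`.
#' @export
read_population <- function(path, years = NULL, bands = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("year", "age_band", "persons")
  if (!all(need %in% names(df)))
    stop("population file ", path, " must have columns ",
         paste(need, collapse = ", "))
  df <- df[need]
  df$year <- as.integer(df$year)
  df$age_band <- as.character(df$age_band)
  df$persons <- as.numeric(df$persons)
  if (anyNA(df)) stop("population file ", path, " contains missing values")
  if (any(df$persons <= 0)) stop("non-positive persons in ", path)
  key <- paste(df$year, df$age_band, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (year, age_band) keys in ", path)
  if (!is.null(bands)) match_bands(df$age_band, bands)
  if (!is.null(years) && !is.null(bands)) {
    gkey <- paste(rep(as.integer(years), each = length(bands)),
                  rep(band_labels(bands), length(years)), sep = "\r")
    miss <- setdiff(gkey, key)
    if (length(miss))
      stop(length(miss), " missing population cells in ", path,
           "; first: ", gsub("\r", " / ", miss[1]))
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_population
#' @param population Data frame with columns `year`, `age_band`, `persons`.
#' @export
write_population <- function(population, path) {
  stopifnot(all(c("year", "age_band", "persons") %in% names(population)))
  utils::write.csv(population[c("year", "age_band", "persons")], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a mortality schedule for life-table construction
#'
#' Reads a national period life table in schedule form: one row per age
#' interval, with columns `age` (interval start, years) and either `mx`
#' (central death rate per person-year) or `qx` (interval death
#' probability), or both. The schedule must start at age 0, be contiguous
#' (no gaps or overlaps), and end in an open terminal interval.
#'
#' @param path CSV path.
#' @return A `data.frame` with columns `age`, `n` (interval width, `Inf`
#'   for the terminal row) and `mx`, sorted by age; class
#'   `mortality_schedule`. When only `qx` is supplied, `mx` is recovered
#'   via the interval relation `mx = qx / (n - (n - ax) * qx)` with the
#'   package's standard separation factors (see [build_life_table()]).
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"age" %in% names(df))
    stop("life table file ", path, " must have an 'age' column")
  has_mx <- "mx" %in% names(df)
  has_qx <- "qx" %in% names(df)
  if (!has_mx && !has_qx)
    stop("life table file ", path, " must have an 'mx' or 'qx' column")
  df <- df[order(df$age), , drop = FALSE]
  age <- as.numeric(df$age)
  if (anyDuplicated(age)) stop("duplicate ages in ", path)
  if (age[1] != 0) stop("life table in ", path, " must start at age 0")
  n <- c(diff(age), Inf)
  if (any(n[-length(n)] <= 0)) stop("non-increasing ages in ", path)
  if (has_mx) {
    mx <- as.numeric(df$mx)
    if (anyNA(mx) || any(mx < 0)) stop("negative or missing mx in ", path)
  } else {
    qx <- as.numeric(df$qx)
    if (anyNA(qx) || any(qx <= 0) || any(qx > 1))
      stop("qx outside (0, 1] in ", path)
    if (qx[length(qx)] != 1)
      stop("terminal interval in ", path, " must have qx = 1")
    k <- length(age)
    ax <- default_ax(age, n)
    mx <- numeric(k)
    cl <- seq_len(k - 1L)
    mx[cl] <- qx[cl] / (n[cl] - (n[cl] - ax[cl]) * qx[cl])
    # terminal mx is not identified by qx = 1; carry the last closed rate
    # forward (everyone in the open interval is exposed at least that hazard)
    mx[k] <- if (k > 1L) mx[k - 1L] else 1
  }
  structure(data.frame(age = age, n = n, mx = mx),
            class = c("mortality_schedule", "data.frame"))
}

#' @rdname read_life_table
#' @param schedule A mortality schedule (columns `age`, `mx`) or a full
#'   [build_life_table()] result.
#' @export
write_life_table <- function(schedule, path) {
  stopifnot("age" %in% names(schedule), "mx" %in% names(schedule))
  keep <- intersect(c("age", "n", "mx", "qx", "ax", "lx", "Lx", "Tx", "ex"),
                    names(schedule))
  utils::write.csv(as.data.frame(schedule)[keep], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Reads a YAML run configuration holding the quantities the analysis takes
#' as external inputs rather than computing: the ICD-10 code set defining
#' the condition, the survey-year range, the standardised mortality ratio
#' applied to population mortality, the pooled SCC-to-DCM conversion rate
#' with its bounds, the age-stratified SCC prevalence curve, and the
#' confidence-interval method.
#'
#' @param path YAML file path.
#' @return A list of class `run_config` with elements `icd_codes`, `years`,
#'   `smr`, `conversion` (list `pooled`, `lower`, `upper`),
#'   `scc_curve` (named numeric: band label -> proportion), `ci_method`
#'   (`"poisson"` or `"binomial"`), `fill_missing`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(icd_codes = c("M47.1", "M50.0", "M99.3", "M99.4", "M99.5"),
                   years = 2012:2018, smr = 1.18, conversion = NULL,
                   scc_curve = NULL, ci_method = "poisson",
                   fill_missing = "error", seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  cfg$years <- as.integer(cfg$years)
  if (!length(cfg$years)) stop("run config: empty year range")
  if (!is.numeric(cfg$smr) || cfg$smr <= 0)
    stop("run config: smr must be a positive number")
  if (!is.null(cfg$conversion)) {
    cv <- cfg$conversion
    if (!(cv$lower > 0 && cv$lower <= cv$pooled && cv$pooled <= cv$upper &&
          cv$upper <= 1))
      stop("run config: conversion rates must satisfy 0 < lower <= pooled <= upper <= 1")
  }
  if (!is.null(cfg$scc_curve)) {
    sc <- unlist(cfg$scc_curve)
    if (any(sc < 0 | sc > 1))
      stop("run config: scc_curve values must be proportions in [0, 1]")
    cfg$scc_curve <- sc
  }
  cfg$ci_method <- match.arg(cfg$ci_method, c("poisson", "binomial"))
  structure(cfg, class = "run_config")
}
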
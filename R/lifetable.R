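#' Separation factors for abridged life tables
#'
#' Average years lived within an interval by those dying in it: n/2 for all
#' closed intervals except the first interval starting at age 0, where early
#' infant mortality concentrates deaths and 0.3 * n is the standard choice.
#' The terminal open interval takes no separation factor (its person-years
#' are lx / mx).
#'
#' @param age Interval start ages.
#' @param n Interval widths (terminal may be `Inf`).
#' @return Numeric vector of ax values (`NA` for the terminal interval).
#' @keywords internal
default_ax <- function(age, n) {
  ax <- n / 2
  if (age[1] == 0) ax[1] <- 0.3 * n[1]
  ax[is.infinite(n)] <- NA_real_
  ax
}

#' Build an abridged period life table
#'
#' Constructs the standard abridged life-table columns from a schedule of
#' central death rates. For closed intervals the death probability is
#' \deqn{q_x = \frac{n\,m_x}{1 + (n - a_x)\,m_x}}
#' with separation factor \eqn{a_x} ([default_ax()]); the terminal open
#' interval has \eqn{q_x = 1} and person-years \eqn{L_x = l_x / m_x}.
#' Survivorship follows \eqn{l_{x+n} = l_x (1 - q_x)} from a radix of
#' 100,000, closed-interval person-years are
#' \eqn{L_x = n\,l_{x+n} + a_x\,d_x}, \eqn{T_x} accumulates \eqn{L_x} from
#' the bottom up, and remaining life expectancy is \eqn{e_x = T_x / l_x}.
#'
#' @param schedule A `mortality_schedule` (from [read_life_table()] or
#'   [simulate_life_table()]) or any data frame with columns `age` and `mx`
#'   (column `n` is recomputed from `age` if absent). Must start at age 0,
#'   be contiguous, and the terminal `mx` must be positive.
#' @param radix Survivors at age 0; the default 100,000 is conventional and
#'   `ex` is invariant to it.
#' @return A data frame of class `life_table` with columns `age`, `n`,
#'   `mx`, `ax`, `qx`, `lx`, `Lx`, `Tx`, `ex`.
#' @examples
#' sched <- data.frame(age = 0:100, mx = 0.02)
#' lt <- build_life_table(sched)
#' lt$ex[1]   # close to 1 / 0.02 = 50 years
#' @seealso [apply_smr()], [duration_at()]
#' @export
build_life_table <- function(schedule, radix = 1e5) {
  stopifnot(all(c("age", "mx") %in% names(schedule)), radix > 0)
  df <- as.data.frame(schedule)[order(schedule$age), , drop = FALSE]
  age <- as.numeric(df$age)
  mx <- as.numeric(df$mx)
  k <- length(age)
  if (k < 1L || age[1] != 0) stop("schedule must start at age 0")
  if (anyNA(mx) || any(mx < 0)) stop("schedule has negative or missing mx")
  n <- c(diff(age), Inf)
  if (any(n[-k] <= 0)) stop("schedule ages must be strictly increasing")
  if (mx[k] <= 0)
    stop("terminal interval must have positive mortality (mx = ", mx[k], ")")
  ax <- default_ax(age, n)
  qx <- numeric(k)
  cl <- seq_len(k - 1L)
  if (k > 1L) qx[cl] <- n[cl] * mx[cl] / (1 + (n[cl] - ax[cl]) * mx[cl])
  qx[k] <- 1
  if (any(qx > 1 + 1e-12)) stop("schedule implies qx > 1; mx too large")
  qx <- pmin(qx, 1)
  lx <- numeric(k)
  lx[1] <- radix
  for (i in seq_len(k - 1L)) lx[i + 1L] <- lx[i] * (1 - qx[i])
  dx <- lx * qx
  Lx <- numeric(k)
  if (k > 1L) Lx[cl] <- n[cl] * c(lx[-1]) + ax[cl] * dx[cl]
  Lx[k] <- lx[k] / mx[k]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  structure(data.frame(age = age, n = n, mx = mx, ax = ax, qx = qx,
                       lx = lx, Lx = Lx, Tx = Tx, ex = ex),
            class = c("life_table", "data.frame"))
}

#' Apply a standardised mortality ratio to a mortality schedule
#'
#' Scales every central death rate by the SMR, then rebuilds the life
#' table: `mx' = smr * mx`. The SMR multiplies rates rather than death
#' probabilities, since an SMR is a ratio of mortality rates and scaling
#' `qx` could exceed 1. `smr = 1` reproduces the unadjusted table exactly.
#'
#' @param schedule As in [build_life_table()].
#' @param smr Positive mortality-rate multiplier (1.18 for DCM).
#' @param radix Passed to [build_life_table()].
#' @return A `life_table` built from the inflated schedule.
#' @examples
#' sched <- data.frame(age = 0:100, mx = 0.05)
#' apply_smr(sched, 1.18)$ex[1]   # close to 1 / 0.059
#' @export
apply_smr <- function(schedule, smr, radix = 1e5) {
  if (!is.numeric(smr) || length(smr) != 1L || smr <= 0)
    stop("smr must be a single positive number")
  adj <- as.data.frame(schedule)[c("age", "mx")]
  adj$mx <- adj$mx * smr
  build_life_table(adj, radix = radix)
}

#' Life expectancy at an exact age
#'
#' Reads `ex` off a life table at any age within its range, interpolating
#' linearly between interval starts. Ages at or beyond the terminal
#' interval start take the terminal `ex`.
#'
#' @param table A `life_table`.
#' @param age Numeric vector of exact ages.
#' @return Remaining life expectancy in years at each age.
#' @export
life_expectancy_at <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  xs <- table$age
  if (any(age < xs[1] | age > max(xs)))
    stop("age outside life-table range [", xs[1], ", ", max(xs), "]")
  stats::approx(xs, table$ex, xout = age, method = "linear",
                rule = 2)$y
}

#' Disease duration for an age band
#'
#' With an incurable condition, expected disease duration from onset equals
#' remaining life expectancy. This evaluates a (typically SMR-adjusted)
#' life table at the band's representative age: the midpoint for closed
#' bands, the lower edge for open bands (see [band_midpoint()]).
#'
#' @param table A `life_table`, usually from [apply_smr()].
#' @param band An [age_band()].
#' @return Duration in years.
#' @export
duration_at <- function(table, band) {
  stopifnot(inherits(band, "age_band"))
  life_expectancy_at(table, band_midpoint(band))
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat("Abridged life table: ", nrow(x), " intervals, age ",
      x$age[1], "-", x$age[nrow(x)], "+, e0 = ",
      format(x$ex[1], digits = digits), " years\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 8), digits = digits, ...)
  if (nrow(x) > 8) cat("... ", nrow(x) - 8, " more rows\n")
  invisible(x)
}
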
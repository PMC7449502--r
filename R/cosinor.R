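#' Cosinor regressors for a day of year
#'
#' Linearization of the single-component cosinor
#' `Y(t) = MESOR + A cos(2*pi*t/tau + phi) + e(t)`:
#' the curve is fit through `beta_c cos(2*pi*t/tau) + beta_s sin(2*pi*t/tau)`
#' with `beta_c = A cos(phi)` and `beta_s = -A sin(phi)`.
#'
#' @param day Day of year (Julian date, 1 = January 1), may be a vector.
#' @param period_days Rhythm period tau in days (default 365, circannual).
#' @return Matrix with columns `cos_t` and `sin_t`.
#' @examples
#' cosinor_regressors(365)  # (1, 0) at the period boundary
#' @export
cosinor_regressors <- function(day, period_days = 365) {
  if (period_days <= 0) stop("'period_days' must be positive")
  w <- 2 * pi * day / period_days
  cbind(cos_t = cos(w), sin_t = sin(w))
}

wrap_phase <- function(phi) {
  r <- phi %% (2 * pi)
  ifelse(r > pi, r - 2 * pi, r)
}

#' Amplitude and acrophase from linearized cosinor coefficients
#'
#' Recovers `A = sqrt(beta_c^2 + beta_s^2)` and
#' `phi = atan2(-beta_s, beta_c)` (normalized to (-pi, pi]) so that
#' `beta_c cos(wt) + beta_s sin(wt) = A cos(wt + phi)` identically. Both
#' coefficients zero gives amplitude 0 with phase defined as 0. Vectorized
#' (used draw-wise on posterior samples).
#'
#' @param beta_cos,beta_sin Coefficients of the cosine and sine regressors.
#' @return List with components `amplitude` and `phase_rad`.
#' @examples
#' amplitude_phase(3, 4)  # amplitude 5
#' @export
amplitude_phase <- function(beta_cos, beta_sin) {
  if (anyNA(beta_cos) || anyNA(beta_sin) ||
      any(!is.finite(beta_cos)) || any(!is.finite(beta_sin)))
    stop("coefficients must be finite")
  list(amplitude = sqrt(beta_cos^2 + beta_sin^2),
       phase_rad = wrap_phase(atan2(-beta_sin, beta_cos)))
}

#' @rdname amplitude_phase
#' @param amplitude Non-negative amplitude.
#' @param phase_rad Acrophase in radians.
#' @export
linear_from_amplitude_phase <- function(amplitude, phase_rad) {
  if (any(amplitude < 0)) stop("'amplitude' must be non-negative")
  list(beta_cos = amplitude * cos(phase_rad),
       beta_sin = -amplitude * sin(phase_rad))
}

#' Bundle cosinor parameters
#'
#' @param mesor Rhythm-adjusted mean (response units).
#' @param amplitude Half the peak-to-trough displacement (>= 0).
#' @param phase_rad Acrophase in radians, normalized to (-pi, pi].
#' @param period_days Period in days (default 365).
#' @return An object of class `cosinor_params`.
#' @export
cosinor_params <- function(mesor, amplitude, phase_rad, period_days = 365) {
  if (amplitude < 0) stop("'amplitude' must be non-negative")
  if (period_days <= 0) stop("'period_days' must be positive")
  structure(list(mesor = mesor, amplitude = amplitude,
                 phase_rad = wrap_phase(phase_rad),
                 period_days = period_days),
            class = "cosinor_params")
}

#' @export
print.cosinor_params <- function(x, ...) {
  cat(sprintf("Cosinor: MESOR %.4g, amplitude %.4g, phase %.4f rad, period %g d\n",
              x$mesor, x$amplitude, x$phase_rad, x$period_days))
  if (x$amplitude > 0) {
    ed <- extremum_days(x)
    cat(sprintf("  peak %s (day %d), trough %s (day %d)\n",
                day_to_calendar(ed["peak_day"]), ed["peak_day"],
                day_to_calendar(ed["trough_day"]), ed["trough_day"]))
  }
  invisible(x)
}

#' Calendar days of the seasonal peak and trough
#'
#' Solves `2*pi*d/tau + phi = 0 (mod 2*pi)` for the day of the maximum; the
#' trough sits half a period later. Days are wrapped to 1..tau and rounded to
#' the nearest integer day (half-up, so day 182.5 reports as 183); a
#' fractional peak wrapping to 0 is reported as day `tau` (the Jan 1
#' boundary).
#'
#' @param p A [cosinor_params] object with positive amplitude.
#' @return Named integer vector `c(peak_day, trough_day)`.
#' @examples
#' extremum_days(cosinor_params(0, 1, -2 * pi * 138 / 365))  # peak day 138
#' @export
extremum_days <- function(p) {
  stopifnot(inherits(p, "cosinor_params"))
  if (p$amplitude <= 0)
    stop("extremum undefined: amplitude is zero")
  tau <- p$period_days
  wrap_day <- function(frac_day) {
    d <- floor((frac_day %% tau) + 0.5)
    if (d == 0 || d > tau) tau else d
  }
  peak_frac <- (-p$phase_rad * tau / (2 * pi)) %% tau
  c(peak_day = as.integer(wrap_day(peak_frac)),
    trough_day = as.integer(wrap_day(peak_frac + tau / 2)))
}

.month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Convert a day of year to a calendar label
#'
#' Non-leap-year convention (365-day calendar, day 1 = January 1).
#'
#' @param day Integer day of year, 1..365.
#' @return Character label, e.g. `"May 18"` for day 138.
#' @export
day_to_calendar <- function(day) {
  day <- as.integer(day)
  if (anyNA(day) || any(day < 1) || any(day > 365))
    stop("'day' must be in 1..365 (non-leap year)")
  ends <- cumsum(.month_days)
  vapply(day, function(d) {
    m <- which(d <= ends)[1]
    paste(month.name[m], d - c(0, ends)[m])
  }, character(1))
}

#' Day of year from a calendar date
#'
#' Parses ISO-8601 dates and maps them onto the package's 365-day calendar
#' (1 = January 1). February 29 of leap years is mapped to day 60 with a
#' warning; later leap-year dates use their non-leap day-of-year so that a
#' given month/day always yields the same index.
#'
#' @param date A `Date`, or a string parseable by `as.Date`.
#' @return Integer day(s) of year in 1..365.
#' @examples
#' julian_day("2015-05-18")  # 138
#' @export
julian_day <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("unparseable date(s); expected ISO-8601 (YYYY-MM-DD)")
  lt <- as.POSIXlt(date)
  mon <- lt$mon + 1L
  mday <- lt$mday
  leap_feb29 <- mon == 2L & mday == 29L
  if (any(leap_feb29)) {
    warning("February 29 mapped to day 60 (non-leap calendar)")
    mday[leap_feb29] <- 28L  # then +1 below lands on 60 via March offset fix
  }
  starts <- c(0, cumsum(.month_days))[seq_len(12)]
  out <- starts[mon] + mday
  out[leap_feb29] <- 60L
  as.integer(out)
}
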
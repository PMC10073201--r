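#' Phase and phase-difference unit helpers
#'
#' Internally all phases are radians; user-facing phase differences (PDs) and
#' periods are hours on a 24 h cycle. The conversion factor is fixed at
#' `24 / (2 * pi)` hours per radian.
#'
#' @param h hours.
#' @param r radians.
#' @return The converted value.
#' @name units
NULL

#' @rdname units
#' @export
hours_to_rad <- function(h) h * pi / 12

#' @rdname units
#' @export
rad_to_hours <- function(r) r * 12 / pi

#' Wrap phase differences to the half-open circadian interval
#'
#' Values are mapped to `(-12, 12]` hours (or `(-pi, pi]` radians), the
#' convention used throughout: adding any multiple of 24 h gives the same
#' wrapped value, and the boundary maps -12 to +12.
#'
#' @param x phase difference(s), hours for `wrap_pd_hours()`, radians for
#'   `wrap_pd_rad()`.
#' @return Wrapped value(s) of the same length.
#' @export
#' @examples
#' wrap_pd_hours(13)   # -11
#' wrap_pd_hours(-12)  # 12
wrap_pd_hours <- function(x) x - 24 * ceiling((x - 12) / 24)

#' @rdname wrap_pd_hours
#' @export
wrap_pd_rad <- function(x) x - 2 * pi * ceiling((x - pi) / (2 * pi))

#' Unwrap a wrapped phase-difference series
#'
#' Removes the 24 h (or 2 pi) jumps a wrapped series shows when the underlying
#' PD drifts across the interval boundary, assuming adjacent samples differ by
#' less than half a cycle.
#'
#' @param x wrapped series.
#' @return Continuous (unwrapped) series with `x[1]` unchanged.
#' @export
unwrap_hours <- function(x) {
  if (length(x) < 2L) return(x)
  x[1] + cumsum(c(0, wrap_pd_hours(diff(x))))
}

#' @rdname unwrap_hours
#' @export
unwrap_rad <- function(x) {
  if (length(x) < 2L) return(x)
  x[1] + cumsum(c(0, wrap_pd_rad(diff(x))))
}

#' Intrinsic angular frequency of an oscillator
#'
#' @param tau intrinsic period in hours; must be positive.
#' @return Angular frequency `2 * pi / tau` in rad/h.
#' @export
#' @examples
#' intrinsic_frequency(24)
intrinsic_frequency <- function(tau) {
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau <= 0)) {
    stop("`tau` must be a finite positive period in hours", call. = FALSE)
  }
  2 * pi / tau
}
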
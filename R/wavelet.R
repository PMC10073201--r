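#' Sinc-filter detrending
#'
#' Removes the slow baseline of a bioluminescence trace by subtracting its
#' low-pass component, computed with a Hamming-windowed sinc FIR filter whose
#' cutoff period is 48 h by default. Oscillations at circadian periods
#' (<= 24 h) pass essentially unattenuated while trends slower than the
#' cutoff are removed; edges are handled by mirror padding.
#'
#' @param x numeric series, uniformly sampled.
#' @param dt sampling step, hours.
#' @param cutoff cutoff period, hours (components slower than this are
#'   treated as trend).
#' @return Detrended series, same length as `x`.
#' @export
#' @examples
#' t <- 0:149
#' y <- cos(2 * pi * t / 24) + 0.02 * t
#' d <- sinc_detrend(y)
sinc_detrend <- function(x, dt = 1, cutoff = 48) {
  stopifnot(is.numeric(x), dt > 0, cutoff > 0)
  n <- length(x)
  M <- ceiling(2 * cutoff / dt)
  if (n <= M) {
    stop(sprintf("series too short for sinc detrending: need > %d samples", M),
         call. = FALSE)
  }
  k <- -M:M
  fc <- dt / cutoff                       # cutoff in cycles per sample
  h <- 2 * fc * sincfun(2 * fc * k)
  h <- h * (0.54 + 0.46 * cos(pi * k / M))  # Hamming window
  h <- h / sum(h)
  # mirror-pad so the convolution is defined up to the edges
  left <- x[(M + 1):2]
  right <- x[(n - 1):(n - M)]
  xp <- c(left, x, right)
  trend <- stats::filter(xp, h, method = "convolution", sides = 2)
  x - as.numeric(trend[(M + 1):(M + n)])
}

sincfun <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Scale-to-period factor. With the amplitude-flat power normalisation used
# below (power ~ exp(-(s*omega - omega0)^2) for a sinusoid of angular
# frequency omega), the power peaks at s = omega0 / omega, so the mapping
# period = scale * 2*pi / omega0 puts a pure sinusoid's argmax exactly at
# its own period. With omega0 = 2*pi, scale and period coincide.
morlet_period_factor <- function(omega0) 2 * pi / omega0

#' Morlet continuous wavelet transform on a period grid
#'
#' Computes the analytic Morlet CWT of a detrended series on a linear grid of
#' `n_periods` periods spanning `[min_period, max_period]` hours. Power is
#' normalised so that a unit-amplitude sinusoid at an on-grid period attains
#' power about 1, with its maximum over the period axis at that period. The
#' mother-wavelet base frequency is `omega0 = 2 * pi`, so scale and period
#' nearly coincide.
#'
#' @param x detrended numeric series.
#' @param dt sampling step, hours.
#' @param min_period,max_period,n_periods period grid, hours.
#' @param omega0 Morlet base angular frequency (dimensionless).
#' @return An object of class `cwt_spectrum`: list with `t`, `periods`,
#'   `power` (periods x time matrix), `coef` (complex coefficients),
#'   `coi_period` (cone-of-influence period per time point), `dt`, `omega0`.
#' @export
cwt_spectrum <- function(x, dt = 1, min_period = 10, max_period = 48,
                         n_periods = 101, omega0 = 2 * pi) {
  stopifnot(is.numeric(x), dt > 0, min_period > 0, max_period > min_period)
  n <- length(x)
  if (n * dt < max_period) {
    stop("series shorter than the longest analysed period", call. = FALSE)
  }
  periods <- seq(min_period, max_period, length.out = n_periods)
  ff <- morlet_period_factor(omega0)
  scales <- periods / ff

  npad <- 2^ceiling(log2(n)) * 2L
  xhat <- stats::fft(c(x - mean(x), rep(0, npad - n)))
  k <- 0:(npad - 1)
  wk <- 2 * pi * k / (npad * dt)
  wk[k > npad / 2] <- 0          # analytic wavelet: positive frequencies only
  pos <- wk > 0

  coef <- matrix(0 + 0i, nrow = n_periods, ncol = n)
  power <- matrix(0, nrow = n_periods, ncol = n)
  for (i in seq_len(n_periods)) {
    s <- scales[i]
    psi_hat <- numeric(npad)
    psi_hat[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * wk[pos] - omega0)^2 / 2)
    w <- stats::fft(xhat * psi_hat, inverse = TRUE)[seq_len(n)] / npad
    coef[i, ] <- w
    power[i, ] <- Mod(w)^2 * 2 * dt / (sqrt(pi) * s)
  }

  t <- (seq_len(n) - 1) * dt
  dist_edge <- pmin(t, t[n] - t)
  coi_period <- ff * dist_edge / sqrt(2)   # e-folding time sqrt(2) * scale
  structure(list(t = t, periods = periods, power = power, coef = coef,
                 coi_period = coi_period, dt = dt, omega0 = omega0),
            class = "cwt_spectrum")
}

#' Maximum-power ridge of a wavelet spectrum
#'
#' Reads the instantaneous period and phase along the ridge of maximal power.
#' The ridge period is the argmax over the period grid, refined to sub-grid
#' resolution by a parabolic fit through the three powers around the maximum;
#' the ridge phase is the argument of the complex coefficient at the argmax,
#' unwrapped along time. Points whose ridge period exceeds the local
#' cone-of-influence period are kept but flagged `in_coi`; averaged
#' statistics exclude them.
#'
#' @param spectrum a `cwt_spectrum`.
#' @param ridge_threshold minimum power to report a ridge point (0 keeps all).
#' @param refine parabolically refine the ridge period to sub-grid
#'   resolution?
#' @return A tibble of class `wavelet_ridge` with columns `t`, `period`
#'   (hours), `phase` (radians, unwrapped), `power`, `in_coi`.
#' @export
extract_ridge <- function(spectrum, ridge_threshold = 0, refine = TRUE) {
  stopifnot(inherits(spectrum, "cwt_spectrum"))
  pw <- spectrum$power
  np <- nrow(pw)
  idx <- apply(pw, 2, which.max)
  j <- seq_len(ncol(pw))
  pmaxv <- pw[cbind(idx, j)]
  period <- spectrum$periods[idx]
  if (refine) {
    # The Morlet response to a sinusoid is Gaussian in scale, so log-power is
    # parabolic around the peak; interpolating it gives sub-grid periods.
    dgrid <- spectrum$periods[2] - spectrum$periods[1]
    inner <- which(idx > 1 & idx < np & pmaxv > 0)
    if (length(inner)) {
      p0 <- log(pmax(pw[cbind(idx[inner] - 1, j[inner])], 1e-300))
      p1 <- log(pmaxv[inner])
      p2 <- log(pmax(pw[cbind(idx[inner] + 1, j[inner])], 1e-300))
      denom <- p0 - 2 * p1 + p2
      shift <- ifelse(denom < 0, 0.5 * (p0 - p2) / denom, 0)
      period[inner] <- period[inner] + pmin(pmax(shift, -0.5), 0.5) * dgrid
    }
  }
  phase <- unwrap_rad(Arg(spectrum$coef[cbind(idx, j)]))
  keep <- pmaxv >= ridge_threshold
  out <- tibble::tibble(
    t = spectrum$t[keep],
    period = period[keep],
    phase = phase[keep],
    power = pmaxv[keep],
    in_coi = period[keep] > spectrum$coi_period[keep]
  )
  class(out) <- c("wavelet_ridge", class(out))
  out
}

#' Phase difference between two wavelet ridges
#'
#' PD(t) = `(phase_i - phase_j) * 24 / (2 * pi)` wrapped to `(-12, 12]` h.
#' Positive values mean oscillator `i` peaks before oscillator `j`.
#'
#' @param ridge_i,ridge_j `wavelet_ridge` objects on the same time grid
#'   (`i` is the reference, typically the AP).
#' @return A tibble with columns `t`, `pd` (hours) and `in_coi` (TRUE where
#'   either ridge is inside its cone of influence).
#' @export
pd_from_ridges <- function(ridge_i, ridge_j) {
  if (length(ridge_i$t) != length(ridge_j$t) ||
      any(abs(ridge_i$t - ridge_j$t) > 1e-9)) {
    stop("ridges must share a time grid", call. = FALSE)
  }
  tibble::tibble(
    t = ridge_i$t,
    pd = wrap_pd_hours(rad_to_hours(ridge_i$phase - ridge_j$phase)),
    in_coi = ridge_i$in_coi | ridge_j$in_coi
  )
}

#' Time-averaged ridge period
#'
#' Mean instantaneous period over a window, excluding points inside the cone
#' of influence (edge-affected samples).
#'
#' @param ridge a `wavelet_ridge`.
#' @param window optional `c(t0, t1)` in hours; default is the whole record.
#' @return Mean period in hours.
#' @export
time_averaged_period <- function(ridge, window = NULL) {
  keep <- !ridge$in_coi
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    keep <- keep & ridge$t >= window[1] & ridge$t <= window[2]
  }
  if (!any(keep)) stop("no ridge samples in the requested window", call. = FALSE)
  mean(ridge$period[keep])
}

#' Full rhythm analysis of a multi-region recording
#'
#' Convenience wrapper running detrend, CWT and ridge extraction for each
#' region column of a recording.
#'
#' @param rec a recording tibble with column `time_h` plus one column per
#'   region (see [read_recording()]).
#' @param cutoff sinc detrend cutoff period, hours.
#' @param min_period,max_period,n_periods CWT period grid, hours.
#' @param ridge_threshold minimum ridge power.
#' @return Named list of `wavelet_ridge` objects, one per region.
#' @export
analyze_recording <- function(rec, cutoff = 48, min_period = 10,
                              max_period = 48, n_periods = 101,
                              ridge_threshold = 0) {
  stopifnot("time_h" %in% names(rec))
  t <- rec$time_h
  dts <- diff(t)
  if (any(abs(dts - dts[1]) > 1e-6 * max(abs(dts[1]), 1))) {
    stop("recording must be uniformly sampled", call. = FALSE)
  }
  regions <- setdiff(names(rec), "time_h")
  out <- lapply(regions, function(rg) {
    d <- sinc_detrend(rec[[rg]], dt = dts[1], cutoff = cutoff)
    sp <- cwt_spectrum(d, dt = dts[1], min_period = min_period,
                       max_period = max_period, n_periods = n_periods)
    extract_ridge(sp, ridge_threshold = ridge_threshold)
  })
  names(out) <- regions
  out
}
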
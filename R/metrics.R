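#' Phase-difference stability score
#'
#' Bins a wrapped PD trace into fixed 15 min bins over `(-12, 12]` h and
#' scores the prominence of the modal bin,
#' `y = max(h_i) / sum(h_i)`. A PD that sits at one value for most of the
#' recording gives `y` near 1; a uniformly drifting PD gives `y` near the
#' uniform floor `1/96`.
#'
#' @param pd wrapped PD values in hours, or a data frame with a `pd` column.
#' @param bin_width histogram bin width, hours (default 0.25 h = 15 min).
#' @return An object of class `stability_score`: list with `y`, `counts`,
#'   `breaks`, `n`.
#' @export
#' @examples
#' stability_score(rep(2, 100))$y   # 1
stability_score <- function(pd, bin_width = 0.25) {
  if (is.data.frame(pd)) pd <- pd$pd
  pd <- pd[is.finite(pd)]
  if (!length(pd)) stop("empty phase-difference trace", call. = FALSE)
  nbins <- round(24 / bin_width)
  if (abs(nbins * bin_width - 24) > 1e-9) {
    stop("`bin_width` must divide 24 h evenly", call. = FALSE)
  }
  x <- wrap_pd_hours(pd)
  idx <- ceiling((x + 12) / bin_width)
  idx[idx < 1L] <- 1L            # guard against floating-point at -12
  counts <- tabulate(idx, nbins = nbins)
  structure(list(y = max(counts) / sum(counts),
                 counts = counts,
                 breaks = seq(-12, 12, by = bin_width),
                 n = length(x)),
            class = "stability_score")
}

#' @export
print.stability_score <- function(x, ...) {
  cat(sprintf("PD stability score y = %.4f (%d samples, %d bins, floor %.4f)\n",
              x$y, x$n, length(x$counts), 1 / length(x$counts)))
  invisible(x)
}

#' Detect constant phase-difference segments
#'
#' A PD channel is in a constant (phase-locked) state wherever the rate of
#' change of the unwrapped PD stays below `rate_threshold` (rad/h) for at
#' least `min_duration` hours. The derivative is taken by centred differences
#' after a short moving-average smoothing (default 3 h window) to suppress
#' sampling ripple. For each maximal qualifying run the segment mean PD
#' `theta_star` is reported, and, when per-oscillator ridges are supplied,
#' the collective period `tau_star` = mean of the two oscillators' mean
#' ridge periods over the segment.
#'
#' @param pd a data frame with columns `t` (hours, uniform grid) and `pd`
#'   (wrapped PD, hours).
#' @param ridge_i,ridge_j optional `wavelet_ridge` objects for the two
#'   oscillators of the channel, used for the collective period.
#' @param rate_threshold locking threshold on `|d theta / dt|`, rad/h.
#' @param min_duration minimum segment length, hours.
#' @param smooth_window moving-average window applied before
#'   differentiation, hours.
#' @return A tibble with one row per segment: `t_start`, `t_end`,
#'   `duration`, `theta_star` (h), `tau_star` (h), `period_i`, `period_j`
#'   (h), `n`. The attribute `multistable` is `TRUE` when more than one
#'   segment qualifies. Zero rows when nothing qualifies.
#' @export
find_constant_pd_segments <- function(pd, ridge_i = NULL, ridge_j = NULL,
                                      rate_threshold = 0.01,
                                      min_duration = 24,
                                      smooth_window = 3) {
  stopifnot(all(c("t", "pd") %in% names(pd)))
  t <- pd$t
  n <- length(t)
  empty <- tibble::tibble(t_start = numeric(), t_end = numeric(),
                          duration = numeric(), theta_star = numeric(),
                          tau_star = numeric(), period_i = numeric(),
                          period_j = numeric(), n = integer())
  attr(empty, "multistable") <- FALSE
  if (n < 3L) return(empty)
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-6)) {
    stop("PD trace must be uniformly sampled", call. = FALSE)
  }
  dt <- dt[1]

  y <- hours_to_rad(unwrap_hours(pd$pd))
  w <- max(1L, round(smooth_window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  ys <- if (w > 1L) as.numeric(stats::filter(y, rep(1 / w, w), sides = 2)) else y
  dy <- rep(NA_real_, n)
  dy[2:(n - 1)] <- (ys[3:n] - ys[1:(n - 2)]) / (2 * dt)
  ok <- !is.na(dy) & abs(dy) < rate_threshold

  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg_idx <- which(r$values & (r$lengths - 1L) * dt >= min_duration)
  if (!length(seg_idx)) return(empty)

  rows <- lapply(seg_idx, function(si) {
    i0 <- starts[si]; i1 <- ends[si]
    th <- wrap_pd_hours(mean(y[i0:i1]) * 12 / pi)
    p_i <- p_j <- NA_real_
    if (!is.null(ridge_i) && !is.null(ridge_j)) {
      win <- c(t[i0], t[i1])
      p_i <- time_averaged_period(ridge_i, win)
      p_j <- time_averaged_period(ridge_j, win)
    }
    tibble::tibble(t_start = t[i0], t_end = t[i1],
                   duration = t[i1] - t[i0],
                   theta_star = th,
                   tau_star = if (is.na(p_i)) NA_real_ else mean(c(p_i, p_j)),
                   period_i = p_i, period_j = p_j,
                   n = i1 - i0 + 1L)
  })
  out <- do.call(rbind, rows)
  attr(out, "multistable") <- nrow(out) > 1L
  out
}

#' Period mismatch of a locked pair
#'
#' Fractional period difference `|tau_i - tau_j| / mean(tau_i, tau_j)` of the
#' two oscillators over a locked segment. Genuinely locked oscillators share
#' a frequency, so the mismatch should be small; a warning (not an error) is
#' issued above the 4% consistency bound.
#'
#' @param period_i,period_j mean periods of the two oscillators over the
#'   segment, hours.
#' @param warn_threshold warning level for the fractional mismatch.
#' @return Fractional mismatch (dimensionless).
#' @export
period_mismatch <- function(period_i, period_j, warn_threshold = 0.04) {
  m <- abs(period_i - period_j) / mean(c(period_i, period_j))
  if (is.finite(m) && m > warn_threshold) {
    warning(sprintf(
      "period mismatch %.1f%% exceeds %.0f%%: segment may not be truly locked",
      100 * m, 100 * warn_threshold), call. = FALSE)
  }
  m
}

#' Select traces suitable for parameter fitting
#'
#' Ranks PD traces by stability score and keeps the most stable ones whose
#' segment structure is unimodal (exactly one locking plateau); traces with
#' several plateaus are ambiguous about which plateau is the steady state and
#' are excluded.
#'
#' @param scores numeric vector of stability scores, one per trace.
#' @param n_segments integer vector, number of detected constant-PD segments
#'   per trace.
#' @param n_keep how many traces to select.
#' @return Integer indices of the selected traces, ordered by decreasing
#'   score.
#' @export
select_fit_traces <- function(scores, n_segments, n_keep = 5) {
  stopifnot(length(scores) == length(n_segments))
  eligible <- which(n_segments == 1L)
  eligible[order(scores[eligible], decreasing = TRUE)][
    seq_len(min(n_keep, length(eligible)))]
}
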
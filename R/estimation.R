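#' Estimate AP-4Vep coupling from a locked plateau
#'
#' For a two-oscillator AP-4Vep system, the steady PD satisfies
#' `sin(theta_av*) = omega_av / K_tilde_av`, so the total coupling follows
#' directly from the plateau value and the intrinsic detuning:
#' `K_tilde_av = omega_av / sin(theta_av*)`. The collective frequency while
#' locked, `Omega_av* = 2 * pi / tau_av*`, fixes the coupling asymmetry
#' `Delta_K_av = K_va - K_av = 2 (Omega_av* - <omega>_av) / sin(theta_av*)`,
#' from which the two directed strengths are recovered.
#'
#' @param theta_star constant AV phase difference, hours.
#' @param tau_a,tau_v intrinsic periods, hours.
#' @param tau_star collective period over the locked segment, hours.
#' @return A list of class `coupling_estimate` with `channel = "av"`,
#'   `K_tilde`, `Delta_K`, `K_av`, `K_va` (rad/h) and the echoed inputs.
#' @export
#' @examples
#' estimate_av(theta_star = 10.17, tau_a = 25.7, tau_v = 23.4,
#'             tau_star = 23.69)
estimate_av <- function(theta_star, tau_a, tau_v, tau_star) {
  w_a <- intrinsic_frequency(tau_a)
  w_v <- intrinsic_frequency(tau_v)
  w_av <- w_a - w_v
  s <- sin(hours_to_rad(theta_star))
  if (abs(s) < 1e-8) {
    stop("sin(theta_av*) is zero: coupling inversion is singular at ",
         "theta* = 0 or +/-12 h", call. = FALSE)
  }
  K_til <- w_av / s
  Omega <- intrinsic_frequency(tau_star)
  dK <- 2 * (Omega - (w_a + w_v) / 2) / s
  structure(list(channel = "av",
                 K_tilde = K_til, Delta_K = dK,
                 K_av = (K_til - dK) / 2, K_va = (K_til + dK) / 2,
                 inputs = list(theta_star = theta_star, tau_a = tau_a,
                               tau_v = tau_v, tau_star = tau_star)),
            class = "coupling_estimate")
}

#' Fit the exponential relaxation rate toward a PD plateau
#'
#' Close to a stable locked state a PD perturbation decays exponentially at
#' the linearisation rate `lambda = -K_tilde_an * cos(theta_an* - gamma)`.
#' The rate is measured by least-squares fitting `y = a * exp(lambda * t) + b`
#' to the unwrapped AN-PD, from the first sample within `approach_tol`
#' radians of the plateau value through the plateau itself (the exponential
#' tail continues inside the detected "constant" segment, and ending the fit
#' at the segment start would leave only the large-amplitude part of the
#' approach, where the sine nonlinearity makes the local rate faster than
#' the linearisation).
#'
#' @param pd a data frame with columns `t` (hours) and `pd` (wrapped AN-PD,
#'   hours).
#' @param theta_star plateau PD, hours; when `NULL` it is taken from the
#'   first segment found by [find_constant_pd_segments()].
#' @param approach_tol radius (radians) around the plateau defining the
#'   start of the fit window.
#' @param min_window minimum fit-window width, hours.
#' @return Fitted rate `lambda` (1/h; negative for a decaying approach),
#'   with the fit object in attribute `fit`.
#' @export
fit_decay_rate <- function(pd, theta_star = NULL,
                           approach_tol = 0.2, min_window = 12) {
  stopifnot(all(c("t", "pd") %in% names(pd)))
  y <- hours_to_rad(unwrap_hours(pd$pd))
  t <- pd$t
  if (is.null(theta_star)) {
    seg <- find_constant_pd_segments(pd)
    if (!nrow(seg)) {
      stop("no constant-PD plateau found to fit an approach to", call. = FALSE)
    }
    theta_star <- seg$theta_star[1]
  }
  th_star <- hours_to_rad(theta_star)
  # map the unwrapped trace onto the plateau's branch
  half <- t >= stats::median(t)
  y <- y - 2 * pi * round((mean(y[half]) - th_star) / (2 * pi))

  i0 <- which(abs(y - th_star) < approach_tol)[1]
  if (is.na(i0)) {
    stop("trajectory never comes within `approach_tol` of the plateau",
         call. = FALSE)
  }
  win <- i0:length(t)
  if (length(win) < 3L || (t[max(win)] - t[min(win)]) < min_window) {
    stop(sprintf("approach window shorter than %g h: cannot fit a decay rate",
                 min_window), call. = FALSE)
  }
  tt <- t[win] - t[win][1]
  yy <- y[win]
  a0 <- yy[1] - th_star
  if (abs(a0) < 1e-4) {
    stop("approach amplitude is degenerate (trace already at the plateau)",
         call. = FALSE)
  }
  fit <- minpack.lm::nlsLM(
    yy ~ a * exp(lambda * tt) + b,
    start = list(a = a0, lambda = -0.05, b = th_star),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  if (abs(cf[["a"]]) < 1e-4) {
    stop("degenerate exponential fit (amplitude ~ 0)", call. = FALSE)
  }
  structure(unname(cf[["lambda"]]), fit = fit)
}

#' Estimate AP-NTS coupling and phase lag from a locked plateau
#'
#' The AN channel has one more parameter than the AV channel (the phase lag
#' `gamma`), so the plateau value alone leaves `(K_tilde_an, gamma)`
#' degenerate. The relaxation rate `lambda` breaks the degeneracy:
#' `K_tilde_an = sqrt(lambda^2 + omega_an^2)`. The lag then follows from the
#' steady state on the stable branch,
#' `gamma = theta_an* - asin(omega_an / K_tilde_an)` (the branch with
#' `cos(theta_an* - gamma) > 0`, consistent with `lambda < 0`), and the
#' asymmetry from the collective frequency:
#' `Delta_K_an = 2 (Omega_an* - <omega>_an) / sin(theta_an* - gamma)`.
#'
#' @param theta_star constant AN phase difference, hours.
#' @param tau_a,tau_n intrinsic periods, hours.
#' @param tau_star collective period over the locked segment, hours.
#' @param lambda relaxation rate from [fit_decay_rate()], 1/h.
#' @return A list of class `coupling_estimate` with `channel = "an"`,
#'   `K_tilde`, `gamma` (rad), `Delta_K`, `K_an`, `K_na`, `lambda` and the
#'   echoed inputs. `Delta_K` is `NA` (with a warning) when
#'   `sin(theta_an* - gamma)` is numerically zero.
#' @export
estimate_an <- function(theta_star, tau_a, tau_n, tau_star, lambda) {
  stopifnot(is.finite(lambda))
  w_a <- intrinsic_frequency(tau_a)
  w_n <- intrinsic_frequency(tau_n)
  w_an <- w_a - w_n
  K_til <- sqrt(lambda^2 + w_an^2)
  marginal <- abs(lambda) < 1e-10
  ratio <- if (K_til > 0) w_an / K_til else 0
  gamma <- wrap_pd_rad(hours_to_rad(theta_star) - asin(ratio))
  s <- sin(hours_to_rad(theta_star) - gamma)   # equals `ratio` by construction
  Omega <- intrinsic_frequency(tau_star)
  if (abs(s) < 1e-8) {
    warning("sin(theta_an* - gamma) = 0: Delta_K is unidentifiable",
            call. = FALSE)
    dK <- NA_real_
  } else {
    dK <- 2 * (Omega - (w_a + w_n) / 2) / s
  }
  structure(list(channel = "an",
                 K_tilde = K_til, gamma = gamma, Delta_K = dK,
                 K_an = (K_til - dK) / 2, K_na = (K_til + dK) / 2,
                 lambda = lambda, marginal = marginal,
                 inputs = list(theta_star = theta_star, tau_a = tau_a,
                               tau_n = tau_n, tau_star = tau_star)),
            class = "coupling_estimate")
}

#' @export
print.coupling_estimate <- function(x, ...) {
  cat(sprintf("Coupling estimate, %s channel\n", toupper(x$channel)))
  cat(sprintf("  K_tilde = %.4g rad/h, Delta_K = %.4g rad/h\n",
              x$K_tilde, x$Delta_K))
  if (x$channel == "an") {
    cat(sprintf("  K_an = %.4g, K_na = %.4g, gamma = %.4g rad, lambda = %.4g /h\n",
                x$K_an, x$K_na, x$gamma, x$lambda))
  } else {
    cat(sprintf("  K_av = %.4g, K_va = %.4g\n", x$K_av, x$K_va))
  }
  invisible(x)
}

#' Recouple the two fitted channels into the three-oscillator model
#'
#' Assembles the full parameter set from the AN and AV channel estimates
#' (with `K_nv = K_vn = 0`) and solves for the stable fixed point of the
#' recoupled PD system at `s = 1`. Because each channel was fitted in
#' isolation, the recoupled fixed point shifts slightly relative to the
#' two-oscillator plateaus; both shifts are reported.
#'
#' @param an_est,av_est `coupling_estimate` objects for the AN and AV
#'   channels.
#' @param tau_a,tau_n,tau_v intrinsic periods, hours.
#' @return A list with `params` (an [osc_params()]), `fixed_point` (one-row
#'   tibble from [fixed_points()], or `NULL` with a warning if no stable
#'   point exists at `s = 1`), and `shift_an`, `shift_av`: recoupled minus
#'   two-oscillator plateau PDs, hours.
#' @export
recouple <- function(an_est, av_est, tau_a, tau_n, tau_v) {
  stopifnot(inherits(an_est, "coupling_estimate"), an_est$channel == "an",
            inherits(av_est, "coupling_estimate"), av_est$channel == "av")
  p <- osc_params(tau_a = tau_a, tau_n = tau_n, tau_v = tau_v,
                  K_an = an_est$K_an, K_na = an_est$K_na,
                  K_av = av_est$K_av, K_va = av_est$K_va,
                  K_nv = 0, K_vn = 0, gamma = an_est$gamma)
  fp <- fixed_points(p, s = 1)
  stable <- fp[fp$stability == "stable", , drop = FALSE]
  if (!nrow(stable)) {
    warning("recoupled system has no stable fixed point at s = 1",
            call. = FALSE)
    return(list(params = p, fixed_point = NULL,
                shift_an = NA_real_, shift_av = NA_real_))
  }
  list(params = p,
       fixed_point = stable[1, ],
       shift_an = wrap_pd_hours(stable$theta_an_h[1] -
                                  an_est$inputs$theta_star),
       shift_av = wrap_pd_hours(stable$theta_av_h[1] -
                                  av_est$inputs$theta_star))
}
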
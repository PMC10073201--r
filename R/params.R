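#' Parameters of the three-oscillator DVC phase model
#'
#' The dorsal vagal complex (DVC) network is modelled as three coupled phase
#' oscillators: the area postrema (`a`), the NTS (`n`, treated as a single
#' oscillator standing for the bilateral pair) and the ependymal layer of the
#' fourth ventricle (`v`). Each has an intrinsic period `tau_i` (hours);
#' `K_ij` (rad/h) is the influence of oscillator `j` on oscillator `i`, and
#' `gamma` (radians) is the AP-NTS interaction phase lag that shifts the
#' locked AN phase difference away from zero.
#'
#' Defaults are the fitted network means shipped with the package (see
#' [default_params()]): NTS-4Vep interactions are taken as negligible, so
#' `K_nv = K_vn = 0`.
#'
#' @param tau_a,tau_n,tau_v intrinsic periods, hours (> 0).
#' @param K_an,K_na,K_av,K_va,K_nv,K_vn directed coupling strengths, rad/h.
#' @param gamma AP-NTS phase lag, radians.
#' @return An object of class `osc_params`.
#' @export
#' @examples
#' p <- osc_params()
#' omega_vec(p)
osc_params <- function(tau_a = 25.7, tau_n = 22.5, tau_v = 23.4,
                       K_an = 0.031, K_na = 0.041,
                       K_av = -0.045, K_va = -0.007,
                       K_nv = 0, K_vn = 0,
                       gamma = 0.770) {
  taus <- c(tau_a = tau_a, tau_n = tau_n, tau_v = tau_v)
  if (any(!is.finite(taus)) || any(taus <= 0)) {
    stop("intrinsic periods must be finite and positive", call. = FALSE)
  }
  Ks <- c(K_an = K_an, K_na = K_na, K_av = K_av, K_va = K_va,
          K_nv = K_nv, K_vn = K_vn)
  if (any(!is.finite(Ks)) || !is.finite(gamma)) {
    stop("coupling strengths and gamma must be finite", call. = FALSE)
  }
  structure(
    list(tau_a = tau_a, tau_n = tau_n, tau_v = tau_v,
         K_an = K_an, K_na = K_na, K_av = K_av, K_va = K_va,
         K_nv = K_nv, K_vn = K_vn, gamma = gamma),
    class = "osc_params"
  )
}

#' @export
print.osc_params <- function(x, ...) {
  cat("DVC three-oscillator phase model parameters\n")
  cat(sprintf("  intrinsic periods (h): AP %.3g  NTS %.3g  4Vep %.3g\n",
              x$tau_a, x$tau_n, x$tau_v))
  cat(sprintf("  coupling (rad/h): K_an %.4g  K_na %.4g  K_av %.4g  K_va %.4g\n",
              x$K_an, x$K_na, x$K_av, x$K_va))
  if (x$K_nv != 0 || x$K_vn != 0) {
    cat(sprintf("                    K_nv %.4g  K_vn %.4g\n", x$K_nv, x$K_vn))
  }
  cat(sprintf("  AN phase lag gamma: %.4g rad (%.3g h)\n",
              x$gamma, rad_to_hours(x$gamma)))
  invisible(x)
}

#' Intrinsic angular frequencies and detunings
#'
#' `omega_vec()` returns the three intrinsic angular frequencies
#' `omega_i = 2 * pi / tau_i`; `detuning()` returns the frequency detuning
#' `omega_ij = omega_i - omega_j` for a named channel.
#'
#' @param params an [osc_params()] object.
#' @param channel `"an"` (AP minus NTS) or `"av"` (AP minus 4Vep).
#' @return Named numeric vector (rad/h) or a single detuning (rad/h).
#' @export
omega_vec <- function(params) {
  c(omega_a = intrinsic_frequency(params$tau_a),
    omega_n = intrinsic_frequency(params$tau_n),
    omega_v = intrinsic_frequency(params$tau_v))
}

#' @rdname omega_vec
#' @export
detuning <- function(params, channel = c("an", "av")) {
  channel <- match.arg(channel)
  w <- omega_vec(params)
  if (channel == "an") unname(w["omega_a"] - w["omega_n"])
  else unname(w["omega_a"] - w["omega_v"])
}

#' Summed and differenced channel coupling
#'
#' `K_tilde()` is the symmetric total coupling `K_ij + K_ji` of a channel;
#' `delta_K()` is the asymmetry `K_(AP -> partner) - K_(partner -> AP)`,
#' i.e. `K_na - K_an` for the AN channel and `K_va - K_av` for AV.
#'
#' @inheritParams omega_vec
#' @return Coupling strength in rad/h.
#' @export
K_tilde <- function(params, channel = c("an", "av")) {
  channel <- match.arg(channel)
  if (channel == "an") params$K_an + params$K_na else params$K_av + params$K_va
}

#' @rdname K_tilde
#' @export
delta_K <- function(params, channel = c("an", "av")) {
  channel <- match.arg(channel)
  if (channel == "an") params$K_na - params$K_an else params$K_va - params$K_av
}

#' Time courses of the global coupling control parameters
#'
#' Each coupling channel carries a dimensionless global control parameter
#' that is either constant or decays linearly to zero:
#' `s_i(t) = max(s0_i - c_i * t, 0)`. `s_n` scales the AP-NTS couplings
#' (`K_an`, `K_na`) and `s_v` the AP-4Vep couplings (`K_av`, `K_va`).
#' `s0 = 1` with `c = 0` reproduces the fitted coupling strengths unchanged.
#'
#' @param s0_n,s0_v initial coupling, dimensionless, >= 0.
#' @param c_n,c_v linear decay rate, per hour, >= 0.
#' @return An object of class `coupling_schedule`.
#' @export
#' @examples
#' sch <- coupling_schedule(s0_n = 1, c_n = 1 / 120)
#' schedule_at(sch, c(0, 60, 120, 180))
coupling_schedule <- function(s0_n = 1, c_n = 0, s0_v = 1, c_v = 0) {
  vals <- c(s0_n = s0_n, c_n = c_n, s0_v = s0_v, c_v = c_v)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("schedule parameters must be finite and non-negative", call. = FALSE)
  }
  structure(list(s0_n = s0_n, c_n = c_n, s0_v = s0_v, c_v = c_v),
            class = "coupling_schedule")
}

#' @rdname coupling_schedule
#' @param schedule a `coupling_schedule`.
#' @param t time(s) in hours.
#' @export
schedule_at <- function(schedule, t) {
  list(s_n = pmax(schedule$s0_n - schedule$c_n * t, 0),
       s_v = pmax(schedule$s0_v - schedule$c_v * t, 0))
}

#' @export
print.coupling_schedule <- function(x, ...) {
  fmt <- function(s0, c) {
    if (c == 0) sprintf("constant %.3g", s0)
    else sprintf("max(%.3g - %.3g t, 0), zero at %.3g h", s0, c, s0 / c)
  }
  cat("Global coupling schedule\n")
  cat("  s_n(t):", fmt(x$s0_n, x$c_n), "\n")
  cat("  s_v(t):", fmt(x$s0_v, x$c_v), "\n")
  invisible(x)
}

#' In-silico NTS hemisection
#'
#' The NTS oscillator stands for a bilateral pair acting symmetrically on the
#' AP; surgically disconnecting one side removes half of the NTS-to-AP drive.
#' The transform therefore halves `K_an` and leaves every other parameter
#' unchanged.
#'
#' @inheritParams omega_vec
#' @return A new `osc_params` with `K_an` halved.
#' @export
disconnection_transform <- function(params) {
  out <- params
  out$K_an <- params$K_an / 2
  out
}
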
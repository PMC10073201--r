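#' Right-hand side of the three-oscillator phase model
#'
#' Phase velocities (rad/h) of the AP, NTS and 4Vep oscillators:
#' \deqn{\dot\theta_a = \omega_a + s_n K_{an} \sin(\theta_n-\theta_a+\gamma)
#'   + s_v K_{av} \sin(\theta_v-\theta_a)}
#' \deqn{\dot\theta_n = \omega_n + s_n K_{na} \sin(\theta_a-\theta_n-\gamma)
#'   + K_{nv} \sin(\theta_v-\theta_n)}
#' \deqn{\dot\theta_v = \omega_v + s_v K_{va} \sin(\theta_a-\theta_v)
#'   + K_{vn} \sin(\theta_n-\theta_v)}
#' The global control parameters `s_n`, `s_v` scale the AP-NTS and AP-4Vep
#' channels respectively; `s_n = s_v = 1` is the fitted network.
#'
#' @param theta numeric length-3 vector `(theta_a, theta_n, theta_v)`, radians.
#' @param params an [osc_params()] object.
#' @param s_n,s_v dimensionless global coupling, >= 0.
#' @return Numeric length-3 vector of phase velocities, rad/h.
#' @export
#' @examples
#' phase_rhs(c(0, 0, 0), osc_params())
phase_rhs <- function(theta, params, s_n = 1, s_v = 1) {
  stopifnot(length(theta) == 3L, all(is.finite(theta)), s_n >= 0, s_v >= 0)
  w <- omega_vec(params)
  ta <- theta[1]; tn <- theta[2]; tv <- theta[3]
  c(w[["omega_a"]] + s_n * params$K_an * sin(tn - ta + params$gamma) +
      s_v * params$K_av * sin(tv - ta),
    w[["omega_n"]] + s_n * params$K_na * sin(ta - tn - params$gamma) +
      params$K_nv * sin(tv - tn),
    w[["omega_v"]] + s_v * params$K_va * sin(ta - tv) +
      params$K_vn * sin(tn - tv))
}

#' Right-hand side of the phase-difference reduction
#'
#' With negligible NTS-4Vep interaction (`K_nv = K_vn = 0`) the model reduces
#' to two phase differences, `theta_an = theta_a - theta_n` and
#' `theta_av = theta_a - theta_v`:
#' \deqn{\dot\theta_{an} = \omega_{an}
#'   - s_n \tilde K_{an} \sin(\theta_{an}-\gamma) - s_v K_{av}\sin\theta_{av}}
#' \deqn{\dot\theta_{av} = \omega_{av}
#'   - s_v \tilde K_{av} \sin\theta_{av} - s_n K_{an}\sin(\theta_{an}-\gamma)}
#' The single-parameter analysis with a common global coupling `s` is the
#' special case `s_n = s_v = s`.
#'
#' @param pd numeric length-2 vector `(theta_an, theta_av)`, radians.
#' @inheritParams phase_rhs
#' @return Numeric length-2 vector of PD velocities, rad/h.
#' @export
pd_rhs <- function(pd, params, s_n = 1, s_v = 1) {
  stopifnot(length(pd) == 2L, all(is.finite(pd)))
  san <- sin(pd[1] - params$gamma)
  sav <- sin(pd[2])
  c(detuning(params, "an") - s_n * K_tilde(params, "an") * san -
      s_v * params$K_av * sav,
    detuning(params, "av") - s_v * K_tilde(params, "av") * sav -
      s_n * params$K_an * san)
}

rk45 <- function() deSolve::rkMethod("rk45dp7")

solve_traj <- function(rhs, init, t_span, output_step, rtol, atol) {
  times <- seq(0, t_span, by = output_step)
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                      method = rk45(), rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    last_t <- if (nrow(sol)) sol[nrow(sol), 1] else NA_real_
    stop(sprintf("integration failed; last valid time %.3g h", last_t),
         call. = FALSE)
  }
  sol
}

#' Simulate the three-oscillator phase model
#'
#' Integrates [phase_rhs()] with the (possibly time-decaying) coupling
#' schedule using an adaptive Runge-Kutta 5(4) (Dormand-Prince) method with
#' relative tolerance `1e-3` and absolute tolerance `1e-6` by default.
#' Phases are returned unwrapped (continuous) on a regular output grid.
#'
#' @param params an [osc_params()] object.
#' @param schedule a [coupling_schedule()]; the default holds both channels
#'   at their fitted strength (`s = 1`).
#' @param init initial phases `(theta_a, theta_n, theta_v)`, radians.
#' @param t_span total simulated time, hours.
#' @param output_step output grid spacing, hours (default 1 h, mirroring
#'   1 h-binned recordings).
#' @param rtol,atol integrator tolerances.
#' @return A tibble of class `phase_traj` with columns `t`, `theta_a`,
#'   `theta_n`, `theta_v` (radians, unwrapped).
#' @export
#' @examples
#' traj <- simulate_phases(osc_params(), t_span = 48)
#' head(phases_to_pd(traj))
simulate_phases <- function(params, schedule = coupling_schedule(),
                            init = c(0, 0, 0), t_span = 150,
                            output_step = 1, rtol = 1e-3, atol = 1e-6) {
  stopifnot(t_span > 0, output_step > 0)
  rhs <- function(t, y, p) {
    s <- schedule_at(schedule, t)
    list(phase_rhs(y, params, s_n = s$s_n, s_v = s$s_v))
  }
  sol <- solve_traj(rhs, init, t_span, output_step, rtol, atol)
  out <- tibble::tibble(t = sol[, 1], theta_a = sol[, 2],
                        theta_n = sol[, 3], theta_v = sol[, 4])
  class(out) <- c("phase_traj", class(out))
  out
}

#' Simulate the phase-difference system directly
#'
#' Integrates [pd_rhs()] on the PD coordinates. By default the two PD
#' channels are wrapped to `(-12, 12]` h; `wrap = FALSE` returns the
#' continuous (unwrapped) PDs in hours, which is what drift-rate analysis
#' needs.
#'
#' @inheritParams simulate_phases
#' @param init initial PDs `(theta_an, theta_av)`, radians.
#' @param wrap wrap output PDs to `(-12, 12]` h?
#' @return A tibble of class `pd_traj` with columns `t`, `pd_an`, `pd_av`
#'   (hours).
#' @export
simulate_pd <- function(params, schedule = coupling_schedule(),
                        init = c(0, 0), t_span = 150, output_step = 1,
                        rtol = 1e-3, atol = 1e-6, wrap = TRUE) {
  stopifnot(t_span > 0, output_step > 0)
  rhs <- function(t, y, p) {
    s <- schedule_at(schedule, t)
    list(pd_rhs(y, params, s_n = s$s_n, s_v = s$s_v))
  }
  sol <- solve_traj(rhs, init, t_span, output_step, rtol, atol)
  an <- rad_to_hours(sol[, 2])
  av <- rad_to_hours(sol[, 3])
  if (wrap) {
    an <- wrap_pd_hours(an)
    av <- wrap_pd_hours(av)
  }
  out <- tibble::tibble(t = sol[, 1], pd_an = an, pd_av = av)
  class(out) <- c("pd_traj", class(out))
  out
}

#' Phase differences of a simulated phase trajectory
#'
#' @param traj a `phase_traj` from [simulate_phases()].
#' @return A tibble of class `pd_traj` with `t`, `pd_an = theta_a - theta_n`
#'   and `pd_av = theta_a - theta_v`, wrapped to `(-12, 12]` hours.
#' @export
phases_to_pd <- function(traj) {
  stopifnot(all(c("t", "theta_a", "theta_n", "theta_v") %in% names(traj)))
  out <- tibble::tibble(
    t = traj$t,
    pd_an = wrap_pd_hours(rad_to_hours(traj$theta_a - traj$theta_n)),
    pd_av = wrap_pd_hours(rad_to_hours(traj$theta_a - traj$theta_v))
  )
  class(out) <- c("pd_traj", class(out))
  out
}
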
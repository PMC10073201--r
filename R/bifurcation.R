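#' Fixed points of the phase-difference system at a given global coupling
#'
#' At a steady state of the PD system the two sines satisfy a linear system:
#' with `u = sin(theta_an - gamma)` and `v = sin(theta_av)`,
#' `A (u, v)' = (omega_an, omega_av)' / s` where
#' `A = [[K_tilde_an, K_av], [K_an, K_tilde_av]]`. If `|u|, |v| <= 1`, the
#' four combinations of arcsine branches give candidate fixed points, each
#' classified by the eigenvalues of the Jacobian
#' `J = -s [[K_tilde_an cos(a), K_av cos(b)], [K_an cos(a), K_tilde_av cos(b)]]`
#' with `a = theta_an - gamma`, `b = theta_av`.
#'
#' @param params an [osc_params()] object.
#' @param s global coupling (applied to both channels), > 0.
#' @param tol eigenvalue tolerance for calling a point marginal.
#' @return A tibble with one row per fixed point: `s`, `theta_an`,
#'   `theta_av` (radians, wrapped), `theta_an_h`, `theta_av_h` (hours),
#'   `eig_max` (largest eigenvalue real part), `stability` (`"stable"`,
#'   `"unstable"`, `"saddle"` or `"fold/neutral"`). Zero rows when no fixed
#'   point exists (coupling below the fold).
#' @export
#' @examples
#' fixed_points(osc_params(), s = 1)
fixed_points <- function(params, s = 1, tol = 1e-9) {
  stopifnot(s > 0)
  A <- coupling_matrix(params)
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(detA) < 1e-14) {
    stop("degenerate coupling: K_tilde_an * K_tilde_av = K_av * K_an, ",
         "the sine-linear system is singular", call. = FALSE)
  }
  rhs <- c(detuning(params, "an"), detuning(params, "av")) / s
  uv <- solve(A, rhs)
  empty <- tibble::tibble(s = numeric(), theta_an = numeric(),
                          theta_av = numeric(), theta_an_h = numeric(),
                          theta_av_h = numeric(), eig_max = numeric(),
                          stability = character())
  if (any(abs(uv) > 1)) return(empty)
  u <- uv[1]; v <- uv[2]
  rows <- list()
  for (flip_an in c(FALSE, TRUE)) {
    for (flip_av in c(FALSE, TRUE)) {
      a <- if (flip_an) pi - asin(u) else asin(u)
      b <- if (flip_av) pi - asin(v) else asin(v)
      J <- -s * A * rbind(c(cos(a), cos(b)), c(cos(a), cos(b)))
      ev <- Re(eigen(J, only.values = TRUE)$values)
      emax <- max(ev); emin <- min(ev)
      stab <- if (abs(emax) <= tol || abs(emin) <= tol) "fold/neutral"
      else if (emax < 0) "stable"
      else if (emin > 0) "unstable"
      else "saddle"
      th_an <- wrap_pd_rad(params$gamma + a)
      th_av <- wrap_pd_rad(b)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        s = s, theta_an = th_an, theta_av = th_av,
        theta_an_h = rad_to_hours(th_an), theta_av_h = rad_to_hours(th_av),
        eig_max = emax, stability = stab)
    }
  }
  do.call(rbind, rows)
}

coupling_matrix <- function(params) {
  matrix(c(K_tilde(params, "an"), params$K_an,
           params$K_av, K_tilde(params, "av")),
         nrow = 2, ncol = 2)
}

#' Closed-form fold location in the global coupling
#'
#' The sine values scale as `u(s) = U / s`, `v(s) = V / s` where `(U, V)`
#' solve the sine-linear system at `s = 1`. Fixed points exist while both
#' magnitudes stay at or below one, so the synchronised state disappears in
#' a fold at `s_fold = max(|U|, |V|)`, where the binding sine reaches +/-1
#' and the Jacobian becomes singular. Zero detuning gives `s_fold = 0`
#' (synchrony at arbitrarily weak coupling).
#'
#' @inheritParams fixed_points
#' @return The fold coupling `s_fold` (dimensionless).
#' @export
#' @examples
#' fold_point(osc_params())
fold_point <- function(params) {
  A <- coupling_matrix(params)
  detA <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(detA) < 1e-14) {
    stop("degenerate coupling: sine-linear system is singular", call. = FALSE)
  }
  UV <- solve(A, c(detuning(params, "an"), detuning(params, "av")))
  max(abs(UV))
}

#' Trace fixed-point branches over a range of global coupling
#'
#' Solves [fixed_points()] on a grid of `s` values. The sine-linear
#' structure makes this exact branch-by-branch continuation; no
#' predictor-corrector is needed, and the grid endpoint of each branch
#' agrees with [fold_point()] to grid resolution.
#'
#' @inheritParams fixed_points
#' @param s_min,s_max range of global coupling.
#' @param n_steps number of grid points.
#' @return A `bifurcation_branch` tibble (rows of [fixed_points()] stacked
#'   over the grid) with attribute `s_fold`.
#' @export
continuation <- function(params, s_min = 0.05, s_max = 1.5, n_steps = 300) {
  stopifnot(s_min > 0, s_max > s_min, n_steps >= 2)
  grid <- seq(s_min, s_max, length.out = n_steps)
  out <- do.call(rbind, lapply(grid, function(s) fixed_points(params, s)))
  attr(out, "s_fold") <- fold_point(params)
  class(out) <- c("bifurcation_branch", class(out))
  out
}

#' Classify PD dynamics across global coupling values
#'
#' Simulates the PD system at each coupling value from shared initial
#' conditions and classifies the long-run behaviour: `"locked"` (settles at
#' a fixed point), `"drifting"` (unwrapped PD grows steadily), or
#' `"plateau_slip"` (a long near-constant plateau punctuated by phase slips,
#' the signature of dynamics just below the fold).
#'
#' @inheritParams fixed_points
#' @param s_values global coupling values to simulate.
#' @param init initial PDs `(theta_an, theta_av)`, radians.
#' @param t_span simulated time per value, hours.
#' @param rate_threshold locking threshold used for plateau detection,
#'   rad/h.
#' @return A tibble with one row per `s`: `s`, `class`, `pd_an_star`,
#'   `pd_av_star` (late-time PDs in hours when locked, else `NA`),
#'   `drift_rate_an`, `drift_rate_av` (late-time unwrapped slope, rad/h).
#'   The simulated trajectories are kept in attribute `trajectories`.
#' @export
sweep_dynamics <- function(params, s_values, init = c(0.5, 2.5),
                           t_span = 250, rate_threshold = 0.01) {
  stopifnot(all(s_values > 0))
  trajs <- list()
  rows <- lapply(seq_along(s_values), function(i) {
    s <- s_values[i]
    traj <- simulate_pd(params, coupling_schedule(s0_n = s, s0_v = s),
                        init = init, t_span = t_span, wrap = FALSE)
    trajs[[i]] <<- traj
    late <- traj$t >= 0.75 * t_span
    slope <- function(col) {
      y <- hours_to_rad(col[late])
      unname(stats::coef(stats::lm(y ~ traj$t[late]))[2])
    }
    r_an <- slope(traj$pd_an)
    r_av <- slope(traj$pd_av)
    locked <- abs(r_an) < 1e-3 && abs(r_av) < 1e-3
    if (locked) {
      cls <- "locked"
      pd_an_star <- wrap_pd_hours(mean(traj$pd_an[late]))
      pd_av_star <- wrap_pd_hours(mean(traj$pd_av[late]))
    } else {
      pd_an_star <- pd_av_star <- NA_real_
      seg <- find_constant_pd_segments(
        tibble::tibble(t = traj$t, pd = wrap_pd_hours(traj$pd_an)),
        rate_threshold = rate_threshold)
      cls <- if (nrow(seg)) "plateau_slip" else "drifting"
    }
    tibble::tibble(s = s, class = cls,
                   pd_an_star = pd_an_star, pd_av_star = pd_av_star,
                   drift_rate_an = r_an, drift_rate_av = r_av)
  })
  out <- do.call(rbind, rows)
  attr(out, "trajectories") <- trajs
  out
}
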
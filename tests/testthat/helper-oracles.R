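# Shared fixtures and independent oracles for the test suite.

ref_params <- function() osc_params()

# Stable fixed point of a single two-oscillator channel, closed form:
# theta* = g + a with sin(a) = omega / K_tilde on the branch where
# K_tilde * cos(a) > 0 (negative linearisation eigenvalue).
two_osc_fixed_point <- function(params, channel) {
  w <- detuning(params, channel)
  Kt <- K_tilde(params, channel)
  g <- if (channel == "an") params$gamma else 0
  a <- asin(w / Kt)
  if (Kt * cos(a) <= 0) a <- pi - a
  wrap_pd_rad(g + a)
}

# Collective frequency of a locked channel (mean-phase equation).
two_osc_collective_tau <- function(params, channel) {
  w <- omega_vec(params)
  mean_w <- if (channel == "an") (w[["omega_a"]] + w[["omega_n"]]) / 2
  else (w[["omega_a"]] + w[["omega_v"]]) / 2
  g <- if (channel == "an") params$gamma else 0
  th <- two_osc_fixed_point(params, channel)
  Omega <- mean_w + delta_K(params, channel) / 2 * sin(th - g)
  2 * pi / Omega
}

# Root of the PD system found by an independent nonlinear solver.
pd_root_oracle <- function(params, s, start) {
  f <- function(x) pd_rhs(x, params, s_n = s, s_v = s)
  pracma::fsolve(f, start)$x
}
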
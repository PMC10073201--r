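test_that("AV estimation inverts exactly on closed-form observables", {
  p <- ref_params()
  th <- rad_to_hours(two_osc_fixed_point(p, "av"))
  tau_star <- two_osc_collective_tau(p, "av")
  est <- estimate_av(th, p$tau_a, p$tau_v, tau_star)
  expect_equal(est$K_tilde, K_tilde(p, "av"), tolerance = 1e-10)
  expect_equal(est$Delta_K, delta_K(p, "av"), tolerance = 1e-10)
  expect_equal(est$K_av, p$K_av, tolerance = 1e-10)
  expect_equal(est$K_va, p$K_va, tolerance = 1e-10)

  # equal collective and mean frequency implies symmetric coupling
  sym <- estimate_av(6, 24, 25, 2 * pi / mean(c(2 * pi / 24, 2 * pi / 25)))
  expect_equal(sym$Delta_K, 0, tolerance = 1e-12)
  expect_equal(sym$K_av, sym$K_va)

  # zero detuning away from the singular angles gives zero total coupling
  z <- estimate_av(6, 24, 24, 24)
  expect_equal(z$K_tilde, 0)

  expect_error(estimate_av(0, 25.7, 23.4, 24), "singular")
  expect_error(estimate_av(12, 25.7, 23.4, 24), "singular")
})

test_that("estimated total AV coupling carries the sign of detuning over sin(PD)", {
  set.seed(14)
  for (i in 1:20) {
    th <- runif(1, -11, 11)
    if (abs(sin(hours_to_rad(th))) < 0.05) next
    tau_a <- runif(1, 22, 27); tau_v <- runif(1, 22, 27)
    if (abs(tau_a - tau_v) < 0.1) next
    est <- estimate_av(th, tau_a, tau_v, mean(c(tau_a, tau_v)))
    w_av <- 2 * pi / tau_a - 2 * pi / tau_v
    expect_equal(sign(est$K_tilde), sign(w_av / sin(hours_to_rad(th))))
  }
})

test_that("AN estimation inverts exactly and satisfies the rate identity", {
  p <- ref_params()
  th <- rad_to_hours(two_osc_fixed_point(p, "an"))
  tau_star <- two_osc_collective_tau(p, "an")
  lam <- -K_tilde(p, "an") * cos(two_osc_fixed_point(p, "an") - p$gamma)
  est <- estimate_an(th, p$tau_a, p$tau_n, tau_star, lam)
  expect_equal(est$K_tilde, K_tilde(p, "an"), tolerance = 1e-10)
  expect_equal(est$gamma, p$gamma, tolerance = 1e-10)
  expect_equal(est$K_an, p$K_an, tolerance = 1e-10)
  expect_equal(est$K_na, p$K_na, tolerance = 1e-10)
  # tautology guard: the identity lambda^2 + omega^2 = K_tilde^2 by construction
  expect_equal(est$K_tilde^2, lam^2 + detuning(p, "an")^2, tolerance = 1e-12)

  # marginal case: lambda = 0 pins K_tilde at |detuning|
  m <- estimate_an(th, p$tau_a, p$tau_n, tau_star, 0)
  expect_equal(m$K_tilde, abs(detuning(p, "an")))
  expect_true(m$marginal)
})

test_that("the exponential fit recovers a known relaxation rate", {
  t <- 0:199
  y_rad <- 1 * exp(-0.0685 * t) + 0.266
  pd <- tibble::tibble(t = t, pd = rad_to_hours(y_rad))
  lam <- fit_decay_rate(pd, theta_star = rad_to_hours(0.266))
  expect_equal(as.numeric(lam), -0.0685, tolerance = 5e-4)

  flat <- tibble::tibble(t = t, pd = rep(rad_to_hours(0.266), 200))
  expect_error(fit_decay_rate(flat, theta_star = rad_to_hours(0.266)),
               "degenerate")
})

test_that("a simulated AN relaxation matches the linearisation rate", {
  p <- ref_params()
  p2 <- p; p2$K_av <- p2$K_va <- 0
  th_star <- two_osc_fixed_point(p2, "an")
  # ~2 h perturbation from the locked state
  pd <- simulate_pd(p2, init = c(th_star + hours_to_rad(2), 0), t_span = 250)
  lam <- fit_decay_rate(tibble::tibble(t = pd$t, pd = pd$pd_an),
                        theta_star = rad_to_hours(th_star))
  lam_lin <- -K_tilde(p, "an") * cos(th_star - p$gamma)
  expect_lt(abs(as.numeric(lam) - lam_lin) / abs(lam_lin), 0.1)
})

test_that("pipeline round trips recover the generating channel parameters", {
  p <- ref_params()
  av <- run_channel_estimation(p, "av")
  expect_lt(abs(av$estimate$K_av - p$K_av) / abs(p$K_av), 0.05)
  expect_lt(abs(av$estimate$K_tilde - K_tilde(p, "av")) /
              abs(K_tilde(p, "av")), 0.05)

  an <- run_channel_estimation(p, "an")
  expect_lt(abs(an$estimate$gamma - p$gamma), 0.05)
  expect_lt(abs(an$estimate$K_na - p$K_na) / p$K_na, 0.05)
  expect_lt(abs(an$estimate$K_tilde - K_tilde(p, "an")) /
              K_tilde(p, "an"), 0.05)
})

test_that("round-trip recovery holds across a box of locked parameter sets", {
  set.seed(31)
  p <- ref_params()
  n_ok <- 0
  for (i in 1:6) {
    q <- p
    q$tau_a <- p$tau_a * runif(1, 0.97, 1.03)
    q$tau_v <- p$tau_v * runif(1, 0.97, 1.03)
    q$K_an <- p$K_an * runif(1, 0.5, 1.5)
    q$K_na <- p$K_na * runif(1, 0.5, 1.5)
    q$K_av <- p$K_av * runif(1, 0.5, 1.5)
    q$K_va <- p$K_va * runif(1, 0.5, 1.5)
    q$gamma <- p$gamma * runif(1, 0.5, 1.5)
    lockable <- abs(detuning(q, "av") / K_tilde(q, "av")) < 0.9 &&
      abs(detuning(q, "an") / K_tilde(q, "an")) < 0.9
    if (!lockable) next
    n_ok <- n_ok + 1
    av <- run_channel_estimation(q, "av", t_span = 250)
    expect_lt(abs(av$estimate$K_tilde - K_tilde(q, "av")) /
                abs(K_tilde(q, "av")), 0.05)
    an <- run_channel_estimation(q, "an", t_span = 250)
    expect_lt(abs(an$estimate$gamma - q$gamma), 0.05)
    expect_lt(abs(an$estimate$K_tilde - K_tilde(q, "an")) /
                abs(K_tilde(q, "an")), 0.05)
  }
  expect_gte(n_ok, 2)
})

test_that("recoupling the fitted channels reproduces the joint steady state", {
  p <- ref_params()
  th_av <- rad_to_hours(two_osc_fixed_point(p, "av"))
  th_an <- rad_to_hours(two_osc_fixed_point(p, "an"))
  av <- estimate_av(th_av, p$tau_a, p$tau_v, two_osc_collective_tau(p, "av"))
  lam <- -K_tilde(p, "an") * cos(two_osc_fixed_point(p, "an") - p$gamma)
  an <- estimate_an(th_an, p$tau_a, p$tau_n, two_osc_collective_tau(p, "an"),
                    lam)
  rc <- recouple(an, av, p$tau_a, p$tau_n, p$tau_v)
  expect_equal(rc$fixed_point$theta_av_h, 10.93, tolerance = 1e-2)
  expect_equal(rc$fixed_point$theta_an_h, 1.74, tolerance = 1e-2)
  # recoupling shifts the AV plateau by about +0.8 h (10.17 -> 10.93)
  expect_equal(rc$shift_av, 10.93 - 10.17, tolerance = 0.05)

  # symmetric degenerate case: no detuning, no lag, no asymmetry
  sym_av <- estimate_av(6, 24, 24, 24)
  sym_an <- structure(list(channel = "an", K_tilde = 0.05, gamma = 0,
                           Delta_K = 0, K_an = 0.025, K_na = 0.025,
                           lambda = -0.05, marginal = FALSE,
                           inputs = list(theta_star = 0)),
                      class = "coupling_estimate")
  sym_av$K_av <- sym_av$K_va <- 0.02
  sym_av$K_tilde <- 0.04; sym_av$Delta_K <- 0
  sym_av$inputs$theta_star <- 0
  rc2 <- recouple(sym_an, sym_av, 24, 24, 24)
  expect_equal(rc2$fixed_point$theta_an, 0, tolerance = 1e-9)
  expect_equal(rc2$fixed_point$theta_av, 0, tolerance = 1e-9)
})
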
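test_that("intrinsic frequency and detunings follow from the periods", {
  expect_equal(intrinsic_frequency(24), 2 * pi / 24)
  expect_equal(intrinsic_frequency(25.7), 0.24448, tolerance = 1e-4)
  p <- ref_params()
  expect_equal(detuning(p, "an"), 2 * pi / 25.7 - 2 * pi / 22.5)
  expect_equal(detuning(p, "an"), -0.03477, tolerance = 1e-3)
  expect_error(intrinsic_frequency(0), "positive")
  expect_error(intrinsic_frequency(-3), "positive")
  expect_error(osc_params(tau_n = -1), "positive")
})

test_that("phase velocities reduce to intrinsic frequencies when coupling vanishes", {
  p <- ref_params()
  p0 <- osc_params(K_an = 0, K_na = 0, K_av = 0, K_va = 0)
  th <- c(1.3, -0.4, 2.2)
  expect_equal(phase_rhs(th, p0), unname(omega_vec(p0)))
  # both AP input sines vanish: NTS sits at -gamma relative, 4Vep in phase
  pa <- osc_params(K_av = 0)
  th2 <- c(0.7, 0.7 - pa$gamma, 0.7)
  expect_equal(phase_rhs(th2, pa)[1], unname(omega_vec(pa)["omega_a"]))
})

test_that("the synchronised fixed point equalises all three phase velocities", {
  p <- ref_params()
  fp <- fixed_points(p, s = 1)
  st <- fp[fp$stability == "stable", ]
  th <- c(0, -st$theta_an, -st$theta_av)
  v <- phase_rhs(th, p)
  expect_lt(max(abs(v - mean(v))), 1e-12)
})

test_that("PD velocities match the oracle root and the uncoupled limit", {
  p <- ref_params()
  expect_equal(pd_rhs(c(0.3, 1.1), p, s_n = 0, s_v = 0),
               c(detuning(p, "an"), detuning(p, "av")))
  root <- pd_root_oracle(p, s = 1, start = c(0.45, 2.9))
  expect_equal(root, c(0.4555, 2.8602), tolerance = 1e-3)
  expect_lt(max(abs(pd_rhs(root, p))), 1e-10)
})

test_that("PD velocities are exactly the differences of phase velocities", {
  p <- ref_params()
  set.seed(11)
  for (i in 1:25) {
    th <- stats::runif(3, -10, 10)
    s <- stats::runif(2, 0, 1.5)
    q <- osc_params(tau_a = runif(1, 20, 30), tau_n = runif(1, 20, 30),
                    tau_v = runif(1, 20, 30),
                    K_an = rnorm(1, 0, 0.05), K_na = rnorm(1, 0, 0.05),
                    K_av = rnorm(1, 0, 0.05), K_va = rnorm(1, 0, 0.05),
                    gamma = runif(1, -1, 1))
    dth <- phase_rhs(th, q, s_n = s[1], s_v = s[2])
    dpd <- pd_rhs(c(th[1] - th[2], th[1] - th[3]), q, s_n = s[1], s_v = s[2])
    expect_equal(dpd, c(dth[1] - dth[2], dth[1] - dth[3]), tolerance = 1e-12)
  }
})

test_that("an uncoupled oscillator advances linearly at its intrinsic rate", {
  p <- ref_params()
  off <- coupling_schedule(0, 0, 0, 0)
  p0 <- p; p0$K_nv <- p0$K_vn <- 0
  traj <- simulate_phases(p0, off, init = c(0.2, 1, -2), t_span = 150)
  expect_equal(traj$theta_n, 1 + 2 * pi / 22.5 * traj$t, tolerance = 1e-8)
  # wrapped AN-PD drifts at the detuning rate and recurs every 2*pi/|omega_an|
  pd <- phases_to_pd(traj)
  slope <- unname(coef(lm(unwrap_hours(pd$pd_an) ~ pd$t))[2])
  expect_equal(hours_to_rad(slope), detuning(p, "an"), tolerance = 1e-6)
  expect_equal(2 * pi / abs(detuning(p, "an")), 180.7, tolerance = 1e-3)
})

test_that("simulating phases then reducing agrees with simulating PDs directly", {
  p <- ref_params()
  set.seed(7)
  init <- runif(3, -pi, pi)
  sch <- coupling_schedule(1, 1 / 250, 1, 0)
  tr3 <- simulate_phases(p, sch, init = init, t_span = 200)
  pd3 <- phases_to_pd(tr3)
  pd2 <- simulate_pd(p, sch, init = c(init[1] - init[2], init[1] - init[3]),
                     t_span = 200)
  err_an <- hours_to_rad(wrap_pd_hours(pd2$pd_an - pd3$pd_an))
  err_av <- hours_to_rad(wrap_pd_hours(pd2$pd_av - pd3$pd_av))
  expect_lt(max(abs(c(err_an, err_av))), 1e-3)
})

test_that("phase differences are invariant to a common phase shift", {
  p <- ref_params()
  init <- c(0.4, -1.2, 2.0)
  a <- phases_to_pd(simulate_phases(p, init = init, t_span = 100))
  b <- phases_to_pd(simulate_phases(p, init = init + 1.7, t_span = 100))
  expect_equal(a$pd_an, b$pd_an, tolerance = 1e-6)
  expect_equal(a$pd_av, b$pd_av, tolerance = 1e-6)
})

test_that("a decaying schedule hands the late-time PD slope to the detuning", {
  p <- ref_params()
  sch <- coupling_schedule(1, 1 / 100, 1, 1 / 100)  # zero from 100 h
  pd <- simulate_pd(p, sch, init = c(0.45, 2.86), t_span = 250, wrap = FALSE)
  late <- pd$t >= 150
  slope <- unname(coef(lm(hours_to_rad(pd$pd_an[late]) ~ pd$t[late]))[2])
  expect_equal(slope, detuning(p, "an"), tolerance = 1e-5)
})

test_that("PD wrapping maps onto the half-open circadian interval", {
  expect_equal(wrap_pd_hours(13), -11)
  expect_equal(wrap_pd_hours(12), 12)
  expect_equal(wrap_pd_hours(-12), 12)
  expect_equal(wrap_pd_hours(0), 0)
  expect_equal(wrap_pd_hours(36), 12)
  x <- seq(-11.9, 12, by = 0.37)
  expect_equal(wrap_pd_hours(x + 24), x)
  expect_equal(rad_to_hours(hours_to_rad(x)), x)
})

test_that("NTS hemisection halves only the NTS-to-AP coupling", {
  p <- ref_params()
  d <- disconnection_transform(p)
  expect_equal(d$K_an, 0.0155)
  expect_equal(d$K_na, 0.041)
  expect_equal(d$K_av, p$K_av)
  # total AN coupling drops by (K_an/2)/K_tilde_an ~ 21.5%
  expect_equal((p$K_an / 2) / K_tilde(p, "an"), 0.215, tolerance = 1e-2)
  expect_equal(disconnection_transform(d)$K_an, 0.00775)
})

test_that("coupling schedules decay linearly and clip at zero", {
  sch <- coupling_schedule(1, 1 / 120, 0.5, 0)
  v <- schedule_at(sch, c(0, 60, 120, 500))
  expect_equal(v$s_n, c(1, 0.5, 0, 0))
  expect_equal(v$s_v, rep(0.5, 4))
  expect_error(coupling_schedule(-0.1, 0, 1, 0), "non-negative")
})
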
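test_that("sinc detrending removes slow trends and keeps circadian oscillations", {
  t <- 0:199
  expect_lt(max(abs(sinc_detrend(rep(3, 200)))), 1e-10)

  y <- cos(2 * pi * t / 24) + 0.01 * t
  d <- sinc_detrend(y)
  interior <- t > 48 & t < 151
  # oscillation preserved within 5%, linear trend removed to < 1% of its range
  expect_lt(max(abs(d[interior] - cos(2 * pi * t / 24)[interior])),
            0.05 + 0.01 * diff(range(0.01 * t)))
  resid <- d[interior] - cos(2 * pi * t / 24)[interior]
  expect_lt(max(abs(resid)), 0.01 * diff(range(0.01 * t)) + 0.05)
  expect_error(sinc_detrend(rep(1, 50)), "too short")
})

test_that("CWT power peaks at the generating period and is amplitude calibrated", {
  t <- 0:199
  x <- cos(2 * pi * t / 24)
  sp <- cwt_spectrum(x, dt = 1)
  mid <- 100
  pk <- sp$periods[which.max(sp$power[, mid])]
  expect_lt(abs(pk - 24), diff(sp$periods[1:2]) + 1e-9)
  expect_equal(max(sp$power[, mid]), 1, tolerance = 0.05)

  # two components give two local maxima near their periods
  x2 <- cos(2 * pi * t / 24) + cos(2 * pi * t / 12)
  sp2 <- cwt_spectrum(x2, dt = 1)
  pw <- sp2$power[, mid]
  locmax <- which(diff(sign(diff(pw))) == -2) + 1
  pers <- sp2$periods[locmax]
  expect_true(any(abs(pers - 24) < 1))
  expect_true(any(abs(pers - 12) < 1))

  expect_equal(max(cwt_spectrum(rep(0, 200), dt = 1)$power), 0)
  expect_error(cwt_spectrum(rep(1, 30), dt = 1), "shorter")
})

test_that("the ridge tracks a chirp monotonically and stays on the period grid", {
  n <- 150
  inst_per <- seq(26, 22, length.out = n)
  phase <- cumsum(2 * pi / inst_per)
  rd <- extract_ridge(cwt_spectrum(cos(phase), dt = 1))
  inner <- rd$period[!rd$in_coi]
  expect_true(all(diff(inner) <= 1e-6))
  expect_true(all(rd$period >= 10 & rd$period <= 48))
})

test_that("ridge phase advances 2*pi per cycle for a pure cosine", {
  t <- 0:199
  rd <- extract_ridge(cwt_spectrum(cos(2 * pi * t / 24), dt = 1))
  inner <- !rd$in_coi
  slope <- unname(coef(lm(rd$phase[inner] ~ rd$t[inner]))[2])
  expect_equal(slope, 2 * pi / 24, tolerance = 1e-3)
})

test_that("ridge phase differences obey the AP-leads-positive sign convention", {
  t <- 0:199
  lead <- 2
  ri <- extract_ridge(cwt_spectrum(cos(2 * pi * (t + lead) / 24), dt = 1))
  rj <- extract_ridge(cwt_spectrum(cos(2 * pi * t / 24), dt = 1))
  pd <- pd_from_ridges(ri, rj)
  expect_equal(mean(pd$pd[!pd$in_coi]), 2, tolerance = 0.05)

  # identical ridges give zero PD
  pd0 <- pd_from_ridges(ri, ri)
  expect_equal(pd0$pd, rep(0, nrow(pd0)))

  # a 13 h lead wraps to -11 h
  ri13 <- extract_ridge(cwt_spectrum(cos(2 * pi * (t + 13) / 24), dt = 1))
  pd13 <- pd_from_ridges(ri13, rj)
  expect_equal(mean(pd13$pd[!pd13$in_coi]), -11, tolerance = 0.1)

  # delaying region j makes PD_ij more positive
  rj_late <- extract_ridge(cwt_spectrum(cos(2 * pi * (t - 1) / 24), dt = 1))
  pd_late <- pd_from_ridges(ri, rj_late)
  expect_gt(mean(pd_late$pd[!pd_late$in_coi]), mean(pd$pd[!pd$in_coi]))

  rj_short <- extract_ridge(cwt_spectrum(cos(2 * pi * t[1:150] / 24), dt = 1))
  expect_error(pd_from_ridges(ri, rj_short), "time grid")
})

test_that("time-averaged period averages the ridge outside the cone of influence", {
  mk <- function(per) {
    structure(tibble::tibble(t = 0:99, period = per, phase = 0, power = 1,
                             in_coi = FALSE),
              class = c("wavelet_ridge", "tbl_df", "tbl", "data.frame"))
  }
  expect_equal(time_averaged_period(mk(rep(25.7, 100))), 25.7)
  expect_equal(time_averaged_period(mk(seq(22, 26, length.out = 100))), 24)
  expect_equal(time_averaged_period(mk(rep(20, 100)), window = c(10, 20)), 20)
  expect_error(time_averaged_period(mk(rep(20, 100)), window = c(200, 300)),
               "window")
})

test_that("the rendering-analysis round trip recovers period and PD", {
  p <- ref_params()
  fp <- fixed_points(p, s = 1)
  st <- fp[fp$stability == "stable", ]
  traj <- simulate_phases(p, init = c(0, -st$theta_an, -st$theta_av),
                          t_span = 200)
  rec <- make_bioluminescence(traj, recording_config(duration = 200,
                                                     noise_sd = 0, seed = 1))
  ridges <- analyze_recording(rec)
  true_period <- 2 * pi / phase_rhs(c(0, -st$theta_an, -st$theta_av), p)[1]
  for (rg in names(ridges)) {
    expect_lt(abs(time_averaged_period(ridges[[rg]]) - true_period) /
                true_period, 0.01)
  }
  pd_av <- pd_from_ridges(ridges$AP, ridges$`4Vep`)
  expect_lt(abs(mean(pd_av$pd[!pd_av$in_coi]) - st$theta_av_h), 0.25)
  pd_an <- pd_from_ridges(ridges$AP, ridges$NTS)
  expect_lt(abs(mean(pd_an$pd[!pd_an$in_coi]) - st$theta_an_h), 0.25)
})
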
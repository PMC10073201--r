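#' Global-coupling sweep of the PD system
#'
#' End-to-end scenario: simulates the PD system over a grid of constant
#' global couplings from shared initial conditions, classifies each run
#' (locked / plateau-then-slip / drifting) and overlays the fixed-point
#' branches from exact continuation. Above the fold, runs started in the
#' basin lock onto the stable branch; below it they drift, with the drift
#' slope approaching the intrinsic detuning as coupling vanishes.
#'
#' @param params an [osc_params()] object.
#' @param s_values global coupling grid.
#' @param init initial PDs `(theta_an, theta_av)`, radians.
#' @param t_span simulated time per coupling value, hours.
#' @return A list with `summary` (the [sweep_dynamics()] table), `branches`
#'   (the [continuation()] table) and `s_fold`.
#' @export
run_coupling_sweep <- function(params = default_params(),
                               s_values = seq(0.1, 1.2, by = 0.05),
                               init = c(0.5, 2.5), t_span = 250) {
  branches <- continuation(params, s_min = min(s_values),
                           s_max = max(s_values), n_steps = 200)
  summary <- sweep_dynamics(params, s_values, init = init, t_span = t_span)
  list(summary = summary, branches = branches,
       s_fold = attr(branches, "s_fold"))
}

classify_segments <- function(n_seg, seg, span) {
  if (n_seg == 0L) "drifting"
  else if (n_seg > 1L) "multi_plateau"
  else if (seg$duration[1] >= 0.8 * span) "constant"
  else "plateau_slip"
}

#' Ensemble study with varied and decaying coupling
#'
#' Runs the full pipeline over a synthetic ensemble: simulate each member
#' (jittered intrinsic periods, schedule drawn from the menu), render a
#' bioluminescence recording, recover ridges by wavelet analysis, compute
#' both PD channels, score their stability, detect constant-PD segments and
#' tabulate time-averaged periods.
#'
#' @param base_params mean model parameters.
#' @param ens an [ensemble_config()].
#' @return A list with `summary` (one row per recording: stability scores,
#'   segment counts, qualitative class per PD channel, time-averaged
#'   periods), `truth` (generator ground truth), `ensemble` (recordings),
#'   and `details` (per-recording ridges, PDs and segment tables).
#' @export
run_decay_ensemble <- function(base_params = default_params(),
                               ens = ensemble_config()) {
  made <- make_ensemble(ens, base_params)
  details <- vector("list", length(made$recordings))
  rows <- vector("list", length(made$recordings))
  for (i in seq_along(made$recordings)) {
    rec <- made$recordings[[i]]
    ridges <- analyze_recording(rec)
    pd_an <- pd_from_ridges(ridges$AP, ridges$NTS)
    pd_av <- pd_from_ridges(ridges$AP, ridges$`4Vep`)
    trim <- function(pd) {
      keep <- !pd$in_coi
      tibble::tibble(t = pd$t[keep], pd = pd$pd[keep])
    }
    pd_an_in <- trim(pd_an)
    pd_av_in <- trim(pd_av)
    seg_an <- find_constant_pd_segments(pd_an_in, ridges$AP, ridges$NTS)
    seg_av <- find_constant_pd_segments(pd_av_in, ridges$AP, ridges$`4Vep`)
    span_an <- diff(range(pd_an_in$t))
    span_av <- diff(range(pd_av_in$t))
    rows[[i]] <- tibble::tibble(
      id = i,
      y_an = stability_score(pd_an_in$pd)$y,
      y_av = stability_score(pd_av_in$pd)$y,
      n_seg_an = nrow(seg_an), n_seg_av = nrow(seg_av),
      class_an = classify_segments(nrow(seg_an), seg_an, span_an),
      class_av = classify_segments(nrow(seg_av), seg_av, span_av),
      period_ap = time_averaged_period(ridges$AP),
      period_nts = time_averaged_period(ridges$NTS),
      period_vep = time_averaged_period(ridges$`4Vep`))
    details[[i]] <- list(ridges = ridges, pd_an = pd_an, pd_av = pd_av,
                         seg_an = seg_an, seg_av = seg_av)
  }
  list(summary = do.call(rbind, rows), truth = made$truth,
       ensemble = made$recordings, details = details)
}

#' Forward-simulate one coupling channel and re-estimate its parameters
#'
#' Recovery experiment for the closed-form estimators: the chosen channel is
#' isolated (the other channel's couplings set to zero), simulated
#' noise-free, rendered as bioluminescence and pushed through the full
#' wavelet pipeline. Plateau observables (`theta*`, `tau*`) are measured on
#' a run started at the channel's locked state; for the AN channel the
#' relaxation rate `lambda` is fitted on a second run started `perturb`
#' radians off the plateau (the approach is fitted on the untrimmed PD,
#' since it largely falls inside the edge cone of influence). The estimators
#' then invert these observables back to coupling parameters, which can be
#' compared against the generating truth.
#'
#' @param params generating parameters ([osc_params()]).
#' @param channel `"av"` or `"an"`.
#' @param t_span simulated length per run, hours.
#' @param perturb initial PD offset for the relaxation run, radians.
#' @param noise_sd observation noise passed to the renderer.
#' @param seed rendering seed.
#' @return A list with `estimate` (a `coupling_estimate`), `measured`
#'   (`theta_star`, `tau_star`, `lambda` in the units of the estimators) and
#'   `truth` (the generating channel parameters).
#' @export
run_channel_estimation <- function(params = default_params(),
                                   channel = c("av", "an"),
                                   t_span = 300, perturb = 1.2,
                                   noise_sd = 0, seed = 1) {
  channel <- match.arg(channel)
  p2 <- params
  if (channel == "av") p2$K_an <- p2$K_na <- 0 else p2$K_av <- p2$K_va <- 0
  w <- detuning(p2, channel)
  Kt <- K_tilde(p2, channel)
  if (abs(Kt) < 1e-12 || abs(w / Kt) > 1) {
    stop("channel cannot lock: |detuning| exceeds the total coupling",
         call. = FALSE)
  }
  g <- if (channel == "an") p2$gamma else 0
  a <- asin(w / Kt)
  if (Kt * cos(a) <= 0) a <- pi - a          # stable branch: K_tilde cos > 0
  th_star <- wrap_pd_rad(g + a)

  partner <- if (channel == "an") "NTS" else "4Vep"
  cfg <- recording_config(duration = t_span, trend = 0, noise_sd = noise_sd,
                          seed = seed)
  observe_pd <- function(offset) {
    init <- c(0, 0, 0)
    init[if (channel == "an") 2 else 3] <- -(th_star + offset)
    traj <- simulate_phases(p2, init = init, t_span = t_span)
    ridges <- analyze_recording(make_bioluminescence(traj, cfg))
    list(ridges = ridges, pd = pd_from_ridges(ridges$AP, ridges[[partner]]))
  }

  plateau <- observe_pd(0)
  keep <- !plateau$pd$in_coi
  pd_in <- tibble::tibble(t = plateau$pd$t[keep], pd = plateau$pd$pd[keep])
  seg <- find_constant_pd_segments(pd_in, plateau$ridges$AP,
                                   plateau$ridges[[partner]])
  if (!nrow(seg)) stop("no constant-PD segment found on the plateau run",
                       call. = FALSE)
  seg <- seg[which.max(seg$duration), ]

  # The relaxation toward the plateau is fast compared with the wavelet's
  # temporal support, which low-passes the transient; the rate is therefore
  # fitted on the PD trajectory itself.
  lambda <- NULL
  if (channel == "an") {
    relax <- simulate_pd(p2, init = c(th_star + perturb, 0), t_span = t_span)
    pd_full <- tibble::tibble(t = relax$t, pd = relax$pd_an)
    lambda <- fit_decay_rate(pd_full, theta_star = seg$theta_star)
  }

  est <- if (channel == "av") {
    estimate_av(seg$theta_star, params$tau_a, params$tau_v, seg$tau_star)
  } else {
    estimate_an(seg$theta_star, params$tau_a, params$tau_n, seg$tau_star,
                as.numeric(lambda))
  }
  truth <- if (channel == "av") {
    list(K_tilde = K_tilde(params, "av"), Delta_K = delta_K(params, "av"),
         K_av = params$K_av, K_va = params$K_va)
  } else {
    list(K_tilde = K_tilde(params, "an"), Delta_K = delta_K(params, "an"),
         K_an = params$K_an, K_na = params$K_na, gamma = params$gamma,
         lambda = -K_tilde(params, "an") * cos(th_star - params$gamma))
  }
  list(channel = channel, estimate = est,
       measured = list(theta_star = seg$theta_star, tau_star = seg$tau_star,
                       lambda = if (is.null(lambda)) NA_real_
                       else as.numeric(lambda)),
       truth = truth)
}

#' In-silico NTS hemisection experiment
#'
#' Simulates three conditions and reports each oscillator's observed period
#' (time-averaged wavelet ridge period of a noise-free rendering):
#' the intact network; the hemisected network (`K_an` halved, giving APx,
#' NTSc and 4Vep); and the disconnected NTS (NTSd), a fully uncoupled NTS
#' oscillator whose observed period is its intrinsic one.
#'
#' @param params an [osc_params()] object.
#' @param duration simulated/observed length, hours.
#' @return A tibble with columns `condition`, `oscillator`, `period_h`.
#' @export
run_disconnection <- function(params = default_params(), duration = 150) {
  fp <- fixed_points(params, s = 1)
  stable <- fp[fp$stability == "stable", , drop = FALSE]
  init <- if (nrow(stable)) c(0, -stable$theta_an[1], -stable$theta_av[1])
  else c(0, 0, 0)
  cfg <- recording_config(duration = duration, trend = 0, noise_sd = 0)

  observe <- function(p) {
    traj <- simulate_phases(p, init = init, t_span = duration)
    rec <- make_bioluminescence(traj, cfg)
    ridges <- analyze_recording(rec)
    vapply(ridges, time_averaged_period, numeric(1))
  }

  per_full <- observe(params)
  per_hemi <- observe(disconnection_transform(params))
  p0 <- params
  p0$K_an <- p0$K_na <- p0$K_av <- p0$K_va <- p0$K_nv <- p0$K_vn <- 0
  per_unc <- observe(p0)

  tibble::tibble(
    condition = c(rep("intact", 3), rep("hemisected", 3), "disconnected"),
    oscillator = c("AP", "NTS", "4Vep", "APx", "NTSc", "4Vep", "NTSd"),
    period_h = c(per_full[["AP"]], per_full[["NTS"]], per_full[["4Vep"]],
                 per_hemi[["AP"]], per_hemi[["NTS"]], per_hemi[["4Vep"]],
                 per_unc[["NTS"]]))
}
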
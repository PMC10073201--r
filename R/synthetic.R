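#' Configuration of a synthetic bioluminescence recording
#'
#' Describes the observation model that turns simulated oscillator phases
#' into PER2::LUC-like intensity traces: a raised cosine of the phase under
#' an exponentially damped amplitude envelope, a slow polynomial baseline,
#' and additive Gaussian noise, sampled on a regular grid (1 h by default,
#' mirroring 1 h-binned recordings).
#'
#' @param duration recording length, hours (>= 72 h for any estimation use).
#' @param sample_step sampling step, hours.
#' @param amplitude named amplitudes (arbitrary units) for regions `AP`,
#'   `NTS`, `4Vep`.
#' @param damping_time e-folding time of the amplitude envelope, hours.
#' @param trend polynomial baseline coefficients `(c0, c1, ...)`, giving
#'   `c0 + c1 t + ...` in intensity units.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed; identical seeds give identical recordings.
#' @return An object of class `recording_config`.
#' @export
recording_config <- function(duration = 150, sample_step = 1,
                             amplitude = c(AP = 1, NTS = 1, `4Vep` = 1),
                             damping_time = 200,
                             trend = c(0.5, -0.002),
                             noise_sd = 0.05,
                             seed = NULL) {
  stopifnot(duration > 0, sample_step > 0, damping_time > 0, noise_sd >= 0)
  structure(list(duration = duration, sample_step = sample_step,
                 amplitude = amplitude, damping_time = damping_time,
                 trend = trend, noise_sd = noise_sd, seed = seed),
            class = "recording_config")
}

poly_eval <- function(coefs, t) {
  out <- numeric(length(t))
  for (k in seq_along(coefs)) out <- out + coefs[k] * t^(k - 1)
  out
}

#' Render simulated phases as a bioluminescence recording
#'
#' For each region `i`, intensity is
#' `B_i(t) = A_i exp(-t / damping_time) (1 + cos(theta_i(t))) + trend(t) +
#' noise`, which is non-negative before noise and peaks when the phase
#' passes zero.
#'
#' @param traj a `phase_traj` from [simulate_phases()] covering at least
#'   `cfg$duration`.
#' @param cfg a [recording_config()].
#' @return A tibble with columns `time_h`, `AP`, `NTS`, `4Vep`.
#' @export
#' @examples
#' traj <- simulate_phases(osc_params(), t_span = 150)
#' rec <- make_bioluminescence(traj, recording_config(noise_sd = 0, seed = 1))
make_bioluminescence <- function(traj, cfg = recording_config()) {
  stopifnot(inherits(cfg, "recording_config"))
  if (max(traj$t) < cfg$duration) {
    stop("trajectory shorter than the requested recording duration",
         call. = FALSE)
  }
  t <- seq(0, cfg$duration, by = cfg$sample_step)
  phases <- list(
    AP = stats::approx(traj$t, traj$theta_a, xout = t)$y,
    NTS = stats::approx(traj$t, traj$theta_n, xout = t)$y,
    `4Vep` = stats::approx(traj$t, traj$theta_v, xout = t)$y
  )
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(cfg$seed)
  }
  env <- exp(-t / cfg$damping_time)
  base <- poly_eval(cfg$trend, t)
  out <- tibble::tibble(time_h = t)
  for (rg in names(phases)) {
    A <- if (rg %in% names(cfg$amplitude)) cfg$amplitude[[rg]] else 1
    eps <- if (cfg$noise_sd > 0) stats::rnorm(length(t), 0, cfg$noise_sd) else 0
    out[[rg]] <- A * env * (1 + cos(phases[[rg]])) + base + eps
  }
  out
}

#' Configuration of a recording ensemble
#'
#' Describes an ensemble of simulated preparations: each member draws
#' jittered AP and 4Vep intrinsic periods (the NTS period is the least
#' variable in practice and is held at its mean), picks a coupling schedule
#' from a menu of constant and linearly decaying time courses, simulates the
#' phase model and renders a bioluminescence recording. The default jitter
#' SDs equal the observed between-preparation period SDs (1.75 h for the AP,
#' 2.03 h for the 4Vep), and the default size of 11 recordings matches the
#' analysed cohort.
#'
#' @param n_recordings ensemble size.
#' @param tau_a_sd,tau_v_sd SD of the Gaussian intrinsic-period jitter,
#'   hours.
#' @param schedule_menu list of [coupling_schedule()]s sampled uniformly.
#' @param seed integer seed fanned out to per-recording substreams.
#' @param recording a [recording_config()] shared by all members.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(n_recordings = 11,
                            tau_a_sd = 1.75, tau_v_sd = 2.03,
                            schedule_menu = default_schedule_menu(),
                            seed = 1,
                            recording = recording_config()) {
  stopifnot(n_recordings >= 1, tau_a_sd >= 0, tau_v_sd >= 0,
            length(schedule_menu) >= 1)
  structure(list(n_recordings = n_recordings, tau_a_sd = tau_a_sd,
                 tau_v_sd = tau_v_sd, schedule_menu = schedule_menu,
                 seed = seed, recording = recording),
            class = "ensemble_config")
}

#' Default menu of coupling schedules
#'
#' Constant global couplings spanning `[0, 1]` plus linear decays that reach
#' zero between 100 and 200 h — the regimes that reproduce the observed
#' menagerie of PD behaviours: persistent locking, immediate drift,
#' plateau-then-slip, and multiple plateaus (which require decaying
#' coupling).
#'
#' @return A list of [coupling_schedule()] objects.
#' @export
default_schedule_menu <- function() {
  list(
    coupling_schedule(1, 0, 1, 0),
    coupling_schedule(0.6, 0, 0.6, 0),
    coupling_schedule(0.3, 0, 0.3, 0),
    coupling_schedule(0.15, 0, 0.15, 0),
    coupling_schedule(0, 0, 0, 0),
    coupling_schedule(1, 1 / 120, 1, 1 / 120),
    coupling_schedule(1, 1 / 160, 1, 1 / 160),
    coupling_schedule(1, 1 / 200, 1, 1 / 200),
    coupling_schedule(1, 0, 1, 1 / 150),
    coupling_schedule(0.8, 0.8 / 140, 0.8, 0.8 / 140)
  )
}

#' Generate a recording ensemble with ground truth
#'
#' @param ens an [ensemble_config()].
#' @param base_params mean model parameters ([osc_params()]); jitter is
#'   applied around `tau_a` and `tau_v`.
#' @return A list with `recordings` (list of recording tibbles), `truth`
#'   (tibble of per-recording parameters: periods, schedule, seed, initial
#'   phases) and `config`. Every member can be regenerated bit-identically
#'   from its `truth` row.
#' @export
make_ensemble <- function(ens = ensemble_config(), base_params = osc_params()) {
  stopifnot(inherits(ens, "ensemble_config"))
  set.seed(ens$seed)
  n <- ens$n_recordings
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n)
  draw_tau <- function(mean, sd) {
    for (i in 1:100) {
      tau <- stats::rnorm(1, mean, sd)
      if (tau > 0) return(tau)
    }
    stop("failed to draw a positive intrinsic period", call. = FALSE)
  }
  rows <- vector("list", n)
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    tau_a <- draw_tau(base_params$tau_a, ens$tau_a_sd)
    tau_v <- draw_tau(base_params$tau_v, ens$tau_v_sd)
    sch_id <- sample.int(length(ens$schedule_menu), 1)
    init <- stats::runif(3, -pi, pi)
    sch <- ens$schedule_menu[[sch_id]]
    p <- base_params
    p$tau_a <- tau_a
    p$tau_v <- tau_v
    traj <- simulate_phases(p, sch, init = init,
                            t_span = ens$recording$duration,
                            output_step = ens$recording$sample_step)
    cfg <- ens$recording
    cfg$seed <- rec_seeds[i]
    recordings[[i]] <- make_bioluminescence(traj, cfg)
    rows[[i]] <- tibble::tibble(
      id = i, seed = rec_seeds[i],
      tau_a = tau_a, tau_n = base_params$tau_n, tau_v = tau_v,
      schedule_id = sch_id,
      s0_n = sch$s0_n, c_n = sch$c_n, s0_v = sch$s0_v, c_v = sch$c_v,
      theta_a0 = init[1], theta_n0 = init[2], theta_v0 = init[3])
  }
  names(recordings) <- sprintf("rec%02d", seq_len(n))
  list(recordings = recordings, truth = do.call(rbind, rows), config = ens)
}

#' Regenerate one ensemble member from its ground-truth row
#'
#' @param truth_row one row of the `truth` tibble from [make_ensemble()].
#' @param ens the [ensemble_config()] used to build the ensemble.
#' @param base_params the base [osc_params()].
#' @return The recording tibble, identical to the originally generated one.
#' @export
regenerate_recording <- function(truth_row, ens, base_params = osc_params()) {
  p <- base_params
  p$tau_a <- truth_row$tau_a
  p$tau_v <- truth_row$tau_v
  sch <- coupling_schedule(truth_row$s0_n, truth_row$c_n,
                           truth_row$s0_v, truth_row$c_v)
  traj <- simulate_phases(
    p, sch,
    init = c(truth_row$theta_a0, truth_row$theta_n0, truth_row$theta_v0),
    t_span = ens$recording$duration,
    output_step = ens$recording$sample_step)
  cfg <- ens$recording
  cfg$seed <- truth_row$seed
  make_bioluminescence(traj, cfg)
}
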
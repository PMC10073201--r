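#!/usr/bin/env Rscript
# Closed-form coupling estimation, validated by forward simulation.
#
# Each coupling channel (AP-NTS with its phase lag, AP-4Vep) is isolated,
# simulated noise-free, rendered as a bioluminescence recording, and pushed
# through the wavelet pipeline. The locked plateau gives theta* and the
# collective period tau*; for the AN channel the relaxation rate lambda is
# fitted from a perturbed run. The closed-form estimators then invert these
# observables; comparing against the generating parameters checks the whole
# measure-then-invert loop. Finally the two fitted channels are recoupled
# into the three-oscillator model.

library(dvcphase)

dir.create("results", showWarnings = FALSE)

params <- default_params()

av <- run_channel_estimation(params, "av")
an <- run_channel_estimation(params, "an")

row <- function(name, est, truth) {
  data.frame(parameter = name, estimated = est, truth = truth,
             rel_error = abs(est - truth) / max(abs(truth), 1e-12))
}
tab <- rbind(
  row("K_av", av$estimate$K_av, params$K_av),
  row("K_va", av$estimate$K_va, params$K_va),
  row("K_tilde_av", av$estimate$K_tilde, K_tilde(params, "av")),
  row("K_an", an$estimate$K_an, params$K_an),
  row("K_na", an$estimate$K_na, params$K_na),
  row("K_tilde_an", an$estimate$K_tilde, K_tilde(params, "an")),
  row("gamma", an$estimate$gamma, params$gamma),
  row("lambda", an$estimate$lambda, an$truth$lambda)
)
print(tab, digits = 3)
cat(sprintf("\nAN plateau %.2f h (collective period %.2f h); AV plateau %.2f h (%.2f h)\n",
            an$measured$theta_star, an$measured$tau_star,
            av$measured$theta_star, av$measured$tau_star))
cat(sprintf("phase lag gamma = %.3f rad = %.2f h on the 24 h cycle\n",
            an$estimate$gamma, rad_to_hours(an$estimate$gamma)))

rc <- recouple(an$estimate, av$estimate, params$tau_a, params$tau_n,
               params$tau_v)
cat(sprintf("recoupled stable state: AN-PD %.2f h, AV-PD %.2f h (AV shift from two-oscillator plateau: %+.2f h)\n",
            rc$fixed_point$theta_an_h, rc$fixed_point$theta_av_h, rc$shift_av))

utils::write.csv(tab, "results/estimation_recovery.csv", row.names = FALSE)
write_params(rc$params, "results/estimated_params.json")
cat("wrote results/estimation_recovery.csv, results/estimated_params.json\n")
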
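#!/usr/bin/env Rscript
# Bifurcation structure of the DVC phase-difference model in the global
# coupling parameter s.
#
# The fitted three-oscillator network is reduced to its two phase
# differences (AN = AP-NTS, AV = AP-4Vep). All couplings are scaled by a
# single dimensionless s; the fixed-point branches are traced exactly via
# the sine-linear structure of the steady state, and the dynamics at
# representative s values are simulated and classified. The synchronised
# state disappears in a fold near s = 0.31: above it trajectories lock
# (AV-PD ~ 10.9 h, AN-PD ~ 1.7 h), just below it long plateaus alternate
# with phase slips (the ghost of the fold), and at weak coupling the PDs
# drift at nearly the intrinsic detuning rate.

library(dvcphase)

dir.create("results", showWarnings = FALSE)

params <- default_params()
out <- run_coupling_sweep(params,
                          s_values = seq(0.10, 1.20, by = 0.05),
                          init = c(0.5, 2.5), t_span = 400)

cat(sprintf("fold of the synchronised state: s_fold = %.4f\n", out$s_fold))
locked <- out$summary[out$summary$class == "locked", ]
cat(sprintf("locked for s >= %.2f; at s = 1 the PDs settle at AN %.2f h, AV %.2f h\n",
            min(locked$s), locked$pd_an_star[locked$s == 1],
            locked$pd_av_star[locked$s == 1]))
cat("classification counts:\n")
print(table(out$summary$class))

utils::write.csv(out$summary, "results/coupling_sweep.csv", row.names = FALSE)
branches <- as.data.frame(out$branches)
num <- vapply(branches, is.numeric, logical(1))
branches[num] <- lapply(branches[num], signif, digits = 6)
utils::write.csv(branches, "results/bifurcation_branches.csv",
                 row.names = FALSE)
jsonlite::write_json(list(s_fold = out$s_fold), "results/fold.json",
                     auto_unbox = TRUE, digits = NA)
cat("wrote results/coupling_sweep.csv, results/bifurcation_branches.csv, results/fold.json\n")
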
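#!/usr/bin/env Rscript
# Ensemble study: jittered intrinsic periods and decaying global coupling.
#
# Eleven synthetic preparations are generated with AP/4Vep period jitter and
# coupling schedules drawn from a menu of constant values and linear decays
# reaching zero between 100 and 200 h (the NTS period is held fixed). Each
# recording goes through the full pipeline — sinc detrend, Morlet CWT,
# ridge, PDs, stability score, constant-PD segments, time-averaged periods.
# The ensemble reproduces the qualitative menagerie seen ex vivo: traces
# that stay locked, traces that drift immediately, plateaus that give way to
# drift as the decaying coupling crosses the fold, and multi-plateau traces.

library(dvcphase)

dir.create("results", showWarnings = FALSE)

params <- default_params()
ens <- ensemble_config(n_recordings = 11, seed = 20260929)
out <- run_decay_ensemble(params, ens)

summary <- merge(out$summary,
                 out$truth[, c("id", "tau_a", "tau_v", "s0_n", "c_n",
                               "s0_v", "c_v")], by = "id")
print(as.data.frame(summary), digits = 3)

cat("\nAN-channel classes:\n")
print(table(summary$class_an))
cat(sprintf("stability scores: AN %.3f-%.3f, AV %.3f-%.3f (uniform floor %.4f)\n",
            min(summary$y_an), max(summary$y_an),
            min(summary$y_av), max(summary$y_av), 1 / 96))
cat(sprintf("observed periods: AP %.1f-%.1f h, NTS %.1f-%.1f h, 4Vep %.1f-%.1f h\n",
            min(summary$period_ap), max(summary$period_ap),
            min(summary$period_nts), max(summary$period_nts),
            min(summary$period_vep), max(summary$period_vep)))

utils::write.csv(summary, "results/ensemble_summary.csv", row.names = FALSE)
utils::write.csv(as.data.frame(out$truth), "results/ensemble_truth.csv",
                 row.names = FALSE)
segs <- do.call(rbind, lapply(seq_along(out$details), function(i) {
  d <- out$details[[i]]
  rbind(
    if (nrow(d$seg_an)) cbind(id = i, channel = "an", as.data.frame(d$seg_an)),
    if (nrow(d$seg_av)) cbind(id = i, channel = "av", as.data.frame(d$seg_av)))
}))
utils::write.csv(segs, "results/ensemble_segments.csv", row.names = FALSE)
cat("wrote results/ensemble_summary.csv, results/ensemble_truth.csv, results/ensemble_segments.csv\n")
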
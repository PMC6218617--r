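#!/usr/bin/env Rscript
# Stage 3 — full synthetic cohorts through the whole pipeline.
#
# Two cohorts of 45 subjects: an "effect" cohort with injected central
# alpha suppression (mean -15% at C3) and task-weakened alpha coupling
# (kappa 4 -> 1), and a matched null cohort with nothing injected. Each
# subject passes through average re-referencing, artifact screening,
# trial-averaged desynchronization at 12 electrodes, C3 alpha-band
# multiscale entropy (N = 14,000, m = 2, r = 0.15 SD, scales 1-20) and the
# 32-channel alpha phase-locking network. Takes a few minutes.

suppressPackageStartupMessages(library(mures))

for (kind in c("effect", "null")) {
  co <- if (kind == "effect") cohort_spec(n_subjects = 45, seed = 1)
        else null_cohort_spec(n_subjects = 45, seed = 1)
  cfg <- pipeline_config(cohort = co,
                         out_dir = file.path("results",
                                             paste0("cohort_", kind)))
  cat("Running", kind, "cohort (n = 45) ...\n")
  bundle <- suppressMessages(run_pipeline(cfg, progress = TRUE))
  cat("  wrote", cfg$out_dir, "-", nrow(bundle$records), "subject records\n")
}
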
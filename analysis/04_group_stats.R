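#!/usr/bin/env Rscript
# Stage 4 — group statistics over the cohort tables from stage 3.
#
# Re-reads the subject records and reports the motor-resonance pattern:
# one-sample t on desynchronization per electrode (Bonferroni threshold
# 0.05/12), paired tests on C3 alpha entropy / alpha global efficiency /
# C3 clustering coefficient, the three regression models for C3
# desynchronization, and the entropy-change vs efficiency-change
# correlation.

suppressPackageStartupMessages(library(mures))

read_records <- function(kind) {
  path <- file.path("results", paste0("cohort_", kind), "subjects.tsv")
  if (!file.exists(path)) stop("run analysis/03_cohorts.R first (missing ",
                               path, ")")
  read.delim(path)
}

report <- function(kind) {
  st <- cohort_stats(read_records(kind))
  cat("\n==", toupper(kind), "cohort ==\n")
  cat(sprintf("Bonferroni threshold (12 comparisons): %.3f\n",
              st$bonferroni$rounded))
  for (el in c("C3", "C4", "O1", "Oz", "O2")) print(st$desync_tests[[el]])
  print(st$entropy_test)
  print(st$ge_test)
  print(st$cc_test)
  for (m in st$models) print(m)
  with(st$change_correlation,
       cat(sprintf("entropy%%-change vs GE%%-change: r = %.3f, t(%d) = %.3f, p = %.3f\n",
                   r, df, t, p)))
  invisible(st)
}

st_eff <- report("effect")
report("null")

cat("\nPattern check (effect cohort): desync C3 negative =",
    st_eff$desync_tests$C3$statistic < 0 & st_eff$desync_tests$C3$p < 0.05,
    "| entropy up =",
    st_eff$entropy_test$statistic > 0 & st_eff$entropy_test$p < 0.05,
    "| alpha GE down =",
    st_eff$ge_test$statistic < 0 & st_eff$ge_test$p < 0.05, "\n")
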
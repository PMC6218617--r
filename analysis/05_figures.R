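#!/usr/bin/env Rscript
# Stage 5 — summary figures: MSE profiles per band (rest vs task) for the
# example subject, and the alpha connectivity matrices per condition.

suppressPackageStartupMessages({
  library(mures)
  library(ggplot2)
})

dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

co <- cohort_spec(n_subjects = 45, seed = 1)
recs <- gen_recording(subject_synth_spec(co, 1))
rest <- rereference_average(recs$rest)
task <- rereference_average(recs$task)

## MSE profiles at C3, raw plus the five bands
profs <- list()
for (b in c(list(NULL), names(default_bands()))) {
  bn <- if (is.null(b[[1]])) "raw" else b
  for (cond in c("rest", "task")) {
    rec <- if (cond == "rest") rest else task
    p <- suppressMessages(
      band_limited_mse(rec, "C3", if (bn == "raw") NULL else bn,
                       n_samples = 14000, condition = cond))
    profs[[length(profs) + 1L]] <-
      data.frame(band = bn, condition = cond,
                 sf = as.integer(names(p$entropy_by_scale)),
                 se = unname(p$entropy_by_scale))
  }
}
df <- do.call(rbind, profs)
df$band <- factor(df$band, c("raw", names(default_bands())))
gg <- ggplot(df, aes(sf, se, colour = condition)) +
  geom_line() + geom_point(size = 0.8) +
  facet_wrap(~band, scales = "free_y") +
  labs(x = "scale factor", y = "sample entropy",
       title = "C3 complexity profiles, rest vs action observation") +
  theme_minimal()
ggsave("results/figures/mse_profiles.pdf", gg, width = 9, height = 6)

## alpha networks
mats <- lapply(list(rest = rest, task = task), function(r)
  build_network(r, "alpha", segment = c(0L, 1000L)))
mdf <- do.call(rbind, lapply(names(mats), function(cond) {
  W <- mats[[cond]]$W
  data.frame(cond = cond, from = rep(rownames(W), ncol(W)),
             to = rep(colnames(W), each = nrow(W)), w = as.vector(W))
}))
mdf$from <- factor(mdf$from, montage_32())
mdf$to <- factor(mdf$to, montage_32())
gh <- ggplot(mdf, aes(from, to, fill = w)) +
  geom_tile() + facet_wrap(~cond) +
  scale_fill_viridis_c(limits = c(0, 1), name = "rPC") +
  theme_minimal() +
  theme(axis.text.x = element_text(angle = 90, vjust = 0.5, size = 5),
        axis.text.y = element_text(size = 5)) +
  labs(title = "Alpha phase-coherence networks (subject 1)")
ggsave("results/figures/alpha_networks.pdf", gh, width = 10, height = 5)

cat("wrote results/figures/{mse_profiles,alpha_networks}.pdf\n")
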
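# Synthetic cohort generation: per-subject ground-truth effects mirroring
# the study design (central alpha suppression during action observation,
# alpha-band phase coupling that weakens during the task).

#' Electrode sets used in the analyses
#'
#' Sensorimotor sites of interest plus frontal, parietal and occipital
#' controls: the 12 electrodes entering the desynchronization tests.
#'
#' @return Character vector of 12 labels.
#' @export
analysis_electrodes <- function() {
  c("C3", "C4", "Cz", "F3", "Fz", "F4", "P3", "Pz", "P4", "O1", "Oz", "O2")
}

#' Synthetic cohort specification
#'
#' Defines the study conditions for an end-to-end simulated cohort. Each
#' subject receives an individual mu-desynchronization magnitude drawn from
#' `N(desync_mean_c3, desync_sd)` at C3 (and `N(desync_mean_c4, desync_sd)`
#' at C4); alpha-band phase coupling forms a star from Cz to the central,
#' frontal and parietal sites with concentration `kappa_rest` at rest and
#' `kappa_task` during the task. All other band amplitudes are identical
#' across conditions. The null preset ([null_cohort_spec()]) injects no
#' effect anywhere.
#'
#' Default amplitudes (µV, peak): alpha 10 at C3/Cz/C4, 12 at O1/Oz/O2,
#' 6 elsewhere; delta 8, theta 6, beta 4, gamma 2 at every channel;
#' 1/f background SD 7 µV. Defaults chosen to give an in-band alpha
#' SNR of roughly 20 at the sensorimotor sites — strong rhythms over a
#' realistic pink background.
#'
#' @param n_subjects cohort size (default 45).
#' @param desync_mean_c3,desync_mean_c4 mean injected desynchronization in
#'   percent (negative = suppression).
#' @param desync_sd between-subject SD of the injected scores.
#' @param kappa_rest,kappa_task von Mises concentrations of the alpha
#'   coupling star per condition.
#' @param noise_amplitude background SD in µV.
#' @param fs sampling rate (Hz).
#' @param duration_rest,duration_task condition durations (s).
#' @param seed root seed; all per-subject randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 45, desync_mean_c3 = -15,
                        desync_mean_c4 = -9, desync_sd = 20,
                        kappa_rest = 4, kappa_task = 1,
                        noise_amplitude = 7, fs = 500,
                        duration_rest = 30, duration_task = 30,
                        seed = 1L) {
  structure(list(n_subjects = as.integer(n_subjects),
                 desync_mean_c3 = desync_mean_c3,
                 desync_mean_c4 = desync_mean_c4,
                 desync_sd = desync_sd,
                 kappa_rest = kappa_rest, kappa_task = kappa_task,
                 noise_amplitude = noise_amplitude, fs = fs,
                 duration_rest = duration_rest,
                 duration_task = duration_task,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @param ... overrides passed to [cohort_spec()].
#' @export
null_cohort_spec <- function(n_subjects = 45, seed = 1L, ...) {
  cohort_spec(n_subjects = n_subjects, desync_mean_c3 = 0,
              desync_mean_c4 = 0, desync_sd = 0,
              kappa_task = 4, kappa_rest = 4, seed = seed, ...)
}

# per-band resting amplitudes for one channel (µV peak)
rest_amplitudes <- function(label) {
  alpha <- if (label %in% c("C3", "Cz", "C4")) 10
           else if (label %in% c("O1", "Oz", "O2")) 12 else 6
  c(delta = 8, theta = 6, alpha = alpha, beta = 4, gamma = 2)
}

alpha_coupling_star <- function(kappa_rest, kappa_task) {
  leaves <- c("C3", "C4", "F3", "Fz", "F4", "P3", "Pz", "P4")
  data.frame(source = "Cz", target = leaves, band = "alpha",
             kappa_rest = kappa_rest, kappa_task = kappa_task)
}

#' Task alpha amplitude realizing a target desynchronization
#'
#' Translates a desired desynchronization score into the task oscillation
#' amplitude, accounting for the 1/f background's in-band power (which the
#' band-power measurement cannot separate from the oscillation): the target
#' is applied to the *total* in-band rest power and the analytic noise
#' floor is subtracted back out before converting to an amplitude.
#'
#' @param rest_amp resting oscillation amplitude (µV peak).
#' @param target_desync desired score in percent.
#' @param noise_sd,noise_beta background parameters.
#' @param n,fs series length and rate used for the exact discrete noise
#'   floor.
#' @param band a [band_definition()] (default alpha).
#' @return Task amplitude in µV (floored at 0 for extreme suppression).
#' @export
task_amplitude_for_desync <- function(rest_amp, target_desync, noise_sd,
                                      noise_beta = 1, n, fs,
                                      band = default_bands()$alpha) {
  floor_p <- noise_sd^2 * pink_band_fraction(n, fs, noise_beta, band)
  rest_total <- rest_amp^2 / 2 + floor_p
  ratio <- power_ratio_for_desync(target_desync, rest_total)
  sqrt(2 * max(0, rest_total * ratio - floor_p))
}

#' Minimal single-subject spec with a known C3 desynchronization
#'
#' A three-channel (C3, Cz, C4) spec carrying an alpha rhythm at C3 whose
#' task amplitude is set (noise-floor corrected, see
#' [task_amplitude_for_desync()]) so that the measured desynchronization
#' score equals `target_desync`. Used for parameter-recovery checks.
#'
#' @param target_desync injected score in percent.
#' @param seed generator seed.
#' @param rest_amp resting alpha amplitude at C3 (µV peak).
#' @param noise_amplitude background SD (µV).
#' @param fs sampling rate (Hz).
#' @param duration_rest,duration_task durations in seconds (defaults cover
#'   a 14,000-sample rest baseline and seven 2-s task epochs).
#' @return A `synth_spec`.
#' @export
recovery_spec <- function(target_desync, seed = 1L, rest_amp = 10,
                          noise_amplitude = 7, fs = 500,
                          duration_rest = 28, duration_task = 14) {
  n_task <- round(duration_task * fs)
  task_amp <- task_amplitude_for_desync(rest_amp, target_desync,
                                        noise_amplitude, 1, n_task, fs)
  amps <- data.frame(channel = "C3", condition = c("rest", "task"),
                     band = "alpha", amplitude = c(rest_amp, task_amp))
  synth_spec(labels = c("C3", "Cz", "C4"), fs = fs,
             duration_rest = duration_rest, duration_task = duration_task,
             band_amplitudes = amps, noise_amplitude = noise_amplitude,
             seed = seed)
}

#' Build one subject's generator spec
#'
#' Draws the subject's injected desynchronization scores from the cohort
#' distribution and assembles the corresponding [synth_spec()]. The
#' injected C3/C4 scores are attached as attribute `"injected"`.
#'
#' @param cohort a [cohort_spec()].
#' @param i subject index in `1..n_subjects`.
#' @return A `synth_spec` with attribute `injected` (named numeric).
#' @export
subject_synth_spec <- function(cohort, i) {
  stopifnot(inherits(cohort, "cohort_spec"), i >= 1, i <= cohort$n_subjects)
  subj_seed <- (cohort$seed %% 100000L) * 20011L + i * 7919L
  set.seed(subj_seed)
  d_c3 <- rnorm(1, cohort$desync_mean_c3, cohort$desync_sd)
  d_c4 <- rnorm(1, cohort$desync_mean_c4, cohort$desync_sd)
  n_task <- round(cohort$duration_task * cohort$fs)
  labels <- montage_32()
  rows <- list()
  for (ch in labels) {
    amps <- rest_amplitudes(ch)
    for (b in names(amps)) {
      task_amp <- amps[[b]]
      if (b == "alpha" && ch %in% c("C3", "C4")) {
        d <- if (ch == "C3") d_c3 else d_c4
        task_amp <- task_amplitude_for_desync(
          amps[[b]], d, cohort$noise_amplitude, 1, n_task, cohort$fs)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, condition = c("rest", "task"), band = b,
        amplitude = c(amps[[b]], task_amp))
    }
  }
  spec <- synth_spec(labels = labels, fs = cohort$fs,
                     duration_rest = cohort$duration_rest,
                     duration_task = cohort$duration_task,
                     band_amplitudes = do.call(rbind, rows),
                     coupling = alpha_coupling_star(cohort$kappa_rest,
                                                    cohort$kappa_task),
                     noise_amplitude = cohort$noise_amplitude,
                     seed = subj_seed + 1L)
  attr(spec, "injected") <- c(C3 = d_c3, C4 = d_c4)
  spec
}

#' Process one synthetic subject end to end
#'
#' Generates the subject's recordings, re-references to the common average,
#' screens artifacts, and computes: trial-averaged desynchronization at the
#' 12 analysis electrodes (7 task epochs of 2 s against the resting
#' baseline), the C3 alpha-band scale-averaged entropy at rest and task
#' (`n_mse` samples, default 14,000), and the alpha phase-coherence
#' network's global efficiency and C3 clustering coefficient for the first
#' 2 s of each condition.
#'
#' @param cohort a [cohort_spec()].
#' @param i subject index.
#' @param n_mse samples entering each MSE profile.
#' @param mse an [mse_params()].
#' @param n_epochs number of 2-s task epochs for the desync average.
#' @return One-row data frame (a subject record).
#' @export
simulate_subject <- function(cohort, i, n_mse = 14000L,
                             mse = mse_params(), n_epochs = 7L) {
  spec <- subject_synth_spec(cohort, i)
  injected <- attr(spec, "injected")
  recs <- gen_recording(spec)
  row <- subject_measures(recs$rest, recs$task, subject = i, n_mse = n_mse,
                          mse = mse, n_epochs = n_epochs)
  row$injected_desync_C3 <- unname(injected["C3"])
  row$injected_desync_C4 <- unname(injected["C4"])
  row
}

#' Measure one subject's record from a rest/task recording pair
#'
#' The measurement half of [simulate_subject()], shared with file-based
#' input: average re-reference, artifact screen, trial-averaged
#' desynchronization, C3 alpha MSE and the alpha network metrics.
#'
#' @param rest_raw,task_raw as-recorded [recording()]s.
#' @param subject subject identifier stored in the record.
#' @inheritParams simulate_subject
#' @return One-row data frame.
#' @export
subject_measures <- function(rest_raw, task_raw, subject = NA_integer_,
                             n_mse = 14000L, mse = mse_params(),
                             n_epochs = 7L) {
  rest <- rereference_average(rest_raw)
  task <- rereference_average(task_raw)
  fs <- rest$fs
  ep_len <- round(2 * fs)

  seg_task <- screen_artifacts(task)
  if (nrow(seg_task) == 0) stop("subject ", subject, ": no clean task data")
  base_on <- seg_task$onset[1]
  onsets <- base_on + (seq_len(n_epochs) - 1L) * ep_len
  epochs <- extract_epochs(task, onsets, ep_len, condition = "task")

  row <- data.frame(subject = subject)
  for (el in analysis_electrodes()) {
    ds <- trial_average_desync(epochs, rest, el, "alpha",
                               rest_samples = min(n_mse, n_samples(rest)))
    row[[paste0("desync_", el)]] <- ds$value
    if (el == "C3") row$mu_power_rest <- ds$rest_power
  }

  prof_rest <- band_limited_mse(rest, "C3", "alpha", mse,
                                n_samples = min(n_mse, n_samples(rest)),
                                condition = "rest")
  prof_task <- band_limited_mse(task, "C3", "alpha", mse,
                                n_samples = min(n_mse, n_samples(task)),
                                condition = "task")
  row$entropy_rest <- prof_rest$avg_entropy
  row$entropy_task <- prof_task$avg_entropy

  g_rest <- build_network(rest, "alpha", segment = c(0L, ep_len),
                          condition = "rest")
  g_task <- build_network(task, "alpha", segment = c(base_on, ep_len),
                          condition = "task")
  row$ge_rest <- global_efficiency(g_rest)
  row$ge_task <- global_efficiency(g_task)
  row$cc_c3_rest <- clustering_coefficient(g_rest, "C3")
  row$cc_c3_task <- clustering_coefficient(g_task, "C3")
  row
}

#' Run a whole synthetic cohort
#'
#' @inheritParams simulate_subject
#' @param cohort a [cohort_spec()].
#' @param progress print a dot per subject.
#' @return Data frame with one subject record per row.
#' @export
run_cohort <- function(cohort, n_mse = 14000L, mse = mse_params(),
                       n_epochs = 7L, progress = FALSE) {
  rows <- lapply(seq_len(cohort$n_subjects), function(i) {
    if (progress) cat(".")
    simulate_subject(cohort, i, n_mse = n_mse, mse = mse,
                     n_epochs = n_epochs)
  })
  if (progress) cat("\n")
  do.call(rbind, rows)
}

#' Group-level statistics for a cohort table
#'
#' One-sample t-tests on desynchronization at every analysis electrode
#' (with the Bonferroni threshold for the 12 comparisons), the paired
#' task-vs-rest tests on C3 alpha entropy, alpha global efficiency and C3
#' clustering coefficient, the three single-predictor regressions of C3
#' desynchronization, and the Pearson correlation between the per-subject
#' percent changes of entropy and of global efficiency.
#'
#' @param records data frame from [run_cohort()].
#' @return List with `desync_tests` (named list of `test_result`s),
#'   `bonferroni`, `entropy_test`, `ge_test`, `cc_test`, `models` (list of
#'   `regression_result`s), `change_correlation`, and the per-subject
#'   `entropy_pct_change` / `ge_pct_change` vectors.
#' @export
cohort_stats <- function(records) {
  desync_tests <- lapply(analysis_electrodes(), function(el) {
    one_sample_t(records[[paste0("desync_", el)]],
                 label = paste0("desync ", el))
  })
  names(desync_tests) <- analysis_electrodes()
  ent_pct <- mapply(percent_change, records$entropy_task,
                    records$entropy_rest)
  ge_pct <- mapply(percent_change_ge, records$ge_task, records$ge_rest)
  list(
    desync_tests = desync_tests,
    bonferroni = bonferroni(0.05, length(desync_tests)),
    entropy_test = paired_t(records$entropy_rest, records$entropy_task,
                            label = "C3 alpha entropy task-rest"),
    ge_test = paired_t(records$ge_rest, records$ge_task,
                       label = "alpha GE task-rest"),
    cc_test = paired_t(records$cc_c3_rest, records$cc_c3_task,
                       label = "C3 alpha CC task-rest"),
    models = list(
      baseline_entropy = regress_desync_on_baseline(records, "baseline_entropy"),
      task_entropy = regress_desync_on_baseline(records, "task_entropy"),
      baseline_power = regress_desync_on_baseline(records, "baseline_power")),
    change_correlation = corr_change(ent_pct, ge_pct),
    entropy_pct_change = ent_pct,
    ge_pct_change = ge_pct
  )
}
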
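# Cohort generation and the end-to-end pipeline driver.

test_that("task amplitudes realize the requested desynchronization", {
  # D = 0 leaves the amplitude untouched
  expect_equal(task_amplitude_for_desync(10, 0, 7, 1, 7000, 500), 10)
  # the floor-corrected total power reproduces the requested ratio
  band <- default_bands()$alpha
  floor_p <- 7^2 * pink_band_fraction(7000, 500, 1, band)
  a <- task_amplitude_for_desync(10, -25, 7, 1, 7000, 500)
  total_rest <- 10^2 / 2 + floor_p
  total_task <- a^2 / 2 + floor_p
  expect_equal(total_task / total_rest,
               power_ratio_for_desync(-25, total_rest), tolerance = 1e-12)
  # extreme suppression floors at zero amplitude rather than going complex
  expect_equal(task_amplitude_for_desync(1.1, -2000, 7, 1, 7000, 500), 0)
})

test_that("subject specs are deterministic and carry their injected effects", {
  co <- cohort_spec(n_subjects = 5, seed = 99)
  s1 <- subject_synth_spec(co, 2)
  s2 <- subject_synth_spec(co, 2)
  expect_identical(s1$band_amplitudes, s2$band_amplitudes)
  expect_identical(attr(s1, "injected"), attr(s2, "injected"))
  s3 <- subject_synth_spec(co, 3)
  expect_false(identical(attr(s1, "injected"), attr(s3, "injected")))
  # a negative injected score shrinks the C3 task alpha amplitude
  inj <- attr(s1, "injected")["C3"]
  amps <- s1$band_amplitudes
  a_rest <- amps$amplitude[amps$channel == "C3" & amps$band == "alpha" &
                             amps$condition == "rest"]
  a_task <- amps$amplitude[amps$channel == "C3" & amps$band == "alpha" &
                             amps$condition == "task"]
  if (inj < 0) expect_lt(a_task, a_rest) else expect_gte(a_task, a_rest)
})

test_that("the null preset injects no effect anywhere", {
  co <- null_cohort_spec(n_subjects = 3, seed = 1)
  spec <- subject_synth_spec(co, 1)
  amps <- spec$band_amplitudes
  rest <- amps[amps$condition == "rest", c("channel", "band", "amplitude")]
  task <- amps[amps$condition == "task", c("channel", "band", "amplitude")]
  expect_equal(rest$amplitude, task$amplitude)
  expect_equal(spec$coupling$kappa_rest, spec$coupling$kappa_task)
})

test_that("a subject record carries every measure the statistics need", {
  co <- cohort_spec(n_subjects = 2, seed = 7, duration_rest = 12,
                    duration_task = 12)
  row <- suppressMessages(
    simulate_subject(co, 1, n_mse = 5000, mse = mse_params(sf_max = 5),
                     n_epochs = 4))
  expect_true(all(paste0("desync_", analysis_electrodes()) %in% names(row)))
  needed <- c("entropy_rest", "entropy_task", "ge_rest", "ge_task",
              "cc_c3_rest", "cc_c3_task", "mu_power_rest",
              "injected_desync_C3")
  expect_true(all(needed %in% names(row)))
  expect_true(all(vapply(row[needed], is.finite, logical(1))))
  expect_gt(row$ge_rest, 0)
})

test_that("cohort_stats assembles the full reporting structure", {
  co <- cohort_spec(n_subjects = 4, seed = 17, duration_rest = 12,
                    duration_task = 12)
  rec <- suppressMessages(run_cohort(co, n_mse = 5000,
                                     mse = mse_params(sf_max = 5),
                                     n_epochs = 4))
  st <- cohort_stats(rec)
  expect_named(st$desync_tests, analysis_electrodes())
  expect_equal(st$bonferroni$rounded, 0.004)
  expect_s3_class(st$entropy_test, "test_result")
  expect_length(st$models, 3)
  expect_true(is.finite(st$change_correlation$r))
  expect_length(st$entropy_pct_change, 4)
})

test_that("pipeline configs fail fast on unknown electrodes", {
  expect_error(pipeline_config(electrodes = c("C3", "C99")), "C99")
})

test_that("run_pipeline is deterministic and writes its bundle", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- function(out) {
    pipeline_config(cohort = cohort_spec(n_subjects = 3, seed = 21,
                                         duration_rest = 12,
                                         duration_task = 12),
                    mse = mse_params(sf_max = 5), n_mse = 5000,
                    n_epochs = 4, out_dir = out)
  }
  b1 <- suppressMessages(run_pipeline(cfg(out1)))
  b2 <- suppressMessages(run_pipeline(cfg(out2)))
  expect_equal(nrow(b1$records), 3)
  expect_identical(b1$records, b2$records)
  for (f in c("subjects.tsv", "tests.tsv", "regression.tsv",
              "change_correlation.tsv", "manifest.json")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
})

test_that("files mode feeds saved recordings through the same measures", {
  co <- cohort_spec(n_subjects = 1, seed = 33, duration_rest = 12,
                    duration_task = 12)
  spec <- subject_synth_spec(co, 1)
  recs <- gen_recording(spec)
  dir <- withr::local_tempdir()
  write_recording(recs$rest, file.path(dir, "s1_rest.tsv"))
  write_recording(recs$task, file.path(dir, "s1_task.tsv"))
  manifest <- data.frame(subject = 1,
                         rest = file.path(dir, "s1_rest.tsv"),
                         task = file.path(dir, "s1_task.tsv"))
  cfg <- pipeline_config(mode = "files", manifest = manifest,
                         mse = mse_params(sf_max = 5), n_mse = 5000,
                         n_epochs = 4)
  bundle_files <- suppressMessages(run_pipeline(cfg))
  direct <- suppressMessages(
    subject_measures(recs$rest, recs$task, subject = 1, n_mse = 5000,
                     mse = mse_params(sf_max = 5), n_epochs = 4))
  expect_equal(bundle_files$records$desync_C3, direct$desync_C3,
               tolerance = 1e-10)
  expect_equal(bundle_files$records$entropy_rest, direct$entropy_rest,
               tolerance = 1e-10)
  # a manifest pointing nowhere is rejected before any computation
  manifest$task <- file.path(dir, "missing.tsv")
  expect_error(pipeline_config(mode = "files", manifest = manifest),
               "missing")
})
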
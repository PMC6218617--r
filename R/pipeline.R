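#' Pipeline configuration
#'
#' A single configuration object driving the end-to-end analysis. In
#' `"synthetic"` mode a cohort is generated from `cohort`; in `"files"`
#' mode `manifest` names per-subject recording files (columns `subject`,
#' `rest`, `task`; matrix or EDF, see [read_recording()]).
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param cohort a [cohort_spec()] (synthetic mode).
#' @param manifest data frame of file paths (files mode).
#' @param electrodes electrodes entering the desynchronization tests; must
#'   resolve against the montage labels.
#' @param mse an [mse_params()].
#' @param n_mse samples per MSE profile (default 14,000).
#' @param n_epochs task epochs averaged for the desync score.
#' @param out_dir output directory for the stage tables; `NULL` disables
#'   writing.
#' @param seed root seed (overrides `cohort$seed` when given).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_spec(), manifest = NULL,
                            electrodes = analysis_electrodes(),
                            mse = mse_params(), n_mse = 14000L,
                            n_epochs = 7L, out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  cfg <- structure(list(mode = mode, cohort = cohort, manifest = manifest,
                        electrodes = electrodes, mse = mse,
                        n_mse = as.integer(n_mse),
                        n_epochs = as.integer(n_epochs),
                        out_dir = out_dir, seed = cohort$seed),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  bad <- setdiff(cfg$electrodes, montage_32())
  if (length(bad)) {
    stop("config names electrodes absent from the montage: ",
         paste(bad, collapse = ", "))
  }
  if (cfg$mode == "files") {
    if (is.null(cfg$manifest)) stop("files mode requires a manifest")
    paths <- c(cfg$manifest$rest, cfg$manifest$task)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("manifest references missing files: ",
           paste(missing, collapse = ", "))
    }
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' generate-or-load, preprocess, spectral, MSE, network, then group
#' statistics, from one config. Deterministic: an identical config (same
#' seed) yields byte-identical machine-readable outputs. When `out_dir` is
#' set, writes `subjects.tsv` (one record per subject), `tests.tsv` (all
#' group-level tests), `regression.tsv` (the three models) and
#' `manifest.json` (seed, config hash, package version).
#'
#' @param config a [pipeline_config()].
#' @param progress print per-subject progress.
#' @return Invisibly, a list with `records`, `stats`, `config`.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  if (config$mode == "files") {
    records <- do.call(rbind, lapply(seq_len(nrow(config$manifest)), function(i) {
      if (progress) cat(".")
      subject_measures(read_recording(config$manifest$rest[i]),
                       read_recording(config$manifest$task[i]),
                       subject = config$manifest$subject[i],
                       n_mse = config$n_mse, mse = config$mse,
                       n_epochs = config$n_epochs)
    }))
    if (progress) cat("\n")
  } else {
    records <- run_cohort(config$cohort, n_mse = config$n_mse,
                          mse = config$mse, n_epochs = config$n_epochs,
                          progress = progress)
  }
  stats <- if (nrow(records) >= 3) cohort_stats(records) else NULL
  if (is.null(stats)) {
    message("fewer than 3 subjects: group statistics skipped")
  }
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(records, stats, config)
  }
  invisible(list(records = records, stats = stats, config = config))
}

test_result_row <- function(tr) {
  data.frame(comparison = tr$label, t = tr$statistic, df = tr$df,
             p = tr$p, d = tr$d, mean = tr$mean, n = tr$n)
}

write_pipeline_outputs <- function(records, stats, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  write.table(format(records, digits = 15), out("subjects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(stats)) {
    write_manifest(records, config, out)
    return(invisible(config$out_dir))
  }
  tests <- do.call(rbind, c(
    lapply(stats$desync_tests, test_result_row),
    list(test_result_row(stats$entropy_test),
         test_result_row(stats$ge_test),
         test_result_row(stats$cc_test))))
  tests$bonferroni_threshold <- stats$bonferroni$threshold
  write.table(format(tests, digits = 10), out("tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- do.call(rbind, lapply(names(stats$models), function(nm) {
    m <- stats$models[[nm]]
    data.frame(model = nm,
               intercept = m$coefficients[1, 1],
               intercept_se = m$coefficients[1, 2],
               slope = m$coefficients[2, 1],
               slope_se = m$coefficients[2, 2],
               slope_p = m$coefficients[2, 4],
               r_squared = m$r_squared, rmse = m$rmse, df = m$df)
  }))
  write.table(format(reg, digits = 10), out("regression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cor_df <- data.frame(r = stats$change_correlation$r,
                       t = stats$change_correlation$t,
                       df = stats$change_correlation$df,
                       p = stats$change_correlation$p)
  write.table(format(cor_df, digits = 10), out("change_correlation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(records, config, out)
  invisible(config$out_dir)
}

write_manifest <- function(records, config, out) {
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  hashed <- config
  hashed$out_dir <- NULL  # hash the scientific config, not the destination
  saveRDS(hashed, cfg_file)
  manifest <- list(seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_file)),
                   n_subjects = nrow(records),
                   package_version = as.character(packageVersion("mures")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
}
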
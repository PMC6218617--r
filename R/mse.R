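#' Multiscale entropy parameters
#'
#' @param m template length (default 2).
#' @param r tolerance as a fraction of the series SD (default 0.15).
#' @param sf_max maximum scale factor (default 20).
#' @return An `mse_params` list.
#' @export
mse_params <- function(m = 2L, r = 0.15, sf_max = 20L) {
  m <- as.integer(m); sf_max <- as.integer(sf_max)
  if (m < 1L) stop("m must be >= 1")
  if (!is.finite(r) || r <= 0 || r >= 1) stop("r must be in (0, 1)")
  if (sf_max < 1L) stop("sf_max must be >= 1")
  structure(list(m = m, r = r, sf_max = sf_max), class = "mse_params")
}

#' Coarse-grain a series
#'
#' Non-overlapping means of `sf` consecutive samples; output length is
#' `floor(N/sf)` and the trailing remainder is discarded. Scale 1 returns
#' the input unchanged.
#'
#' @param x numeric series.
#' @param sf scale factor, `1 <= sf <= length(x)`.
#' @return Coarse-grained series of length `floor(length(x)/sf)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
coarse_grain <- function(x, sf) {
  sf <- as.integer(sf)
  if (sf < 1L) stop("sf must be >= 1")
  n <- length(x)
  if (sf > n) stop("sf (", sf, ") exceeds series length (", n, ")")
  if (sf == 1L) return(x)
  ncg <- n %/% sf
  colMeans(matrix(x[seq_len(ncg * sf)], nrow = sf))
}

#' Sample entropy
#'
#' `SE = -ln(A/B)` where `B` counts pairs of m-point templates within
#' Chebyshev distance `< r_abs` and `A` the subset whose next points also
#' match; self-matches excluded. Undefined (returned as `NA`) when no
#' template pair matches at either length — including degenerate
#' (constant) input — never an exception.
#'
#' @param x numeric series of length `> m + 1`.
#' @param m template length.
#' @param r_abs absolute tolerance (same units as `x`), `> 0`.
#' @return SE value `>= 0`, or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 2L, r_abs) {
  m <- as.integer(m)
  if (length(x) <= m + 1L) stop("series length must exceed m + 1")
  if (!is.finite(r_abs) || r_abs <= 0) stop("r_abs must be > 0")
  ab <- sampen_counts(as.numeric(x), m, r_abs)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[1] / ab[2])
}

#' Multiscale entropy profile
#'
#' Sample entropy at every scale factor `1..sf_max` of the coarse-grained
#' series, with the absolute tolerance fixed once as `r` times the SD of
#' the original (scale-1) series and reused at all scales (the standard MSE
#' convention; set `per_scale_r = TRUE` to renormalize per scale). The
#' scale-averaged entropy is the mean over defined scales; undefined scales
#' carry `NA` and are excluded from the average with a message.
#'
#' @param x numeric series.
#' @param params an [mse_params()].
#' @param per_scale_r recompute `r_abs` from each coarse-grained series' SD
#'   instead of the scale-1 SD (default `FALSE`).
#' @return An `mse_profile`: list with `entropy_by_scale` (named numeric,
#'   `NA` = undefined), `avg_entropy`, `params`, and `electrode`, `band`,
#'   `condition` annotations (filled by [band_limited_mse()]).
#' @export
mse_curve <- function(x, params = mse_params(), per_scale_r = FALSE) {
  stopifnot(inherits(params, "mse_params"))
  n <- length(x)
  if (n %/% params$sf_max < 100) {
    warning("only ", n %/% params$sf_max, " coarse-grained points at ",
            "sf_max = ", params$sf_max,
            "; < 100 points gives unreliable sample entropy")
  }
  sd1 <- stats::sd(x)
  se <- rep(NA_real_, params$sf_max)
  names(se) <- seq_len(params$sf_max)
  for (sf in seq_len(params$sf_max)) {
    cg <- coarse_grain(x, sf)
    if (length(cg) <= params$m + 1L) break
    r_abs <- if (per_scale_r) params$r * stats::sd(cg) else params$r * sd1
    if (!is.finite(r_abs) || r_abs <= 0) next  # degenerate series: flag NA
    se[sf] <- sample_entropy(cg, params$m, r_abs)
  }
  if (anyNA(se)) {
    message(sum(is.na(se)), " of ", params$sf_max,
            " scales undefined; averaging over defined scales only")
  }
  avg <- if (all(is.na(se))) NA_real_ else mean(se, na.rm = TRUE)
  structure(list(entropy_by_scale = se, avg_entropy = avg, params = params,
                 electrode = NA_character_, band = NA_character_,
                 condition = NA_character_),
            class = "mse_profile")
}

#' @export
print.mse_profile <- function(x, ...) {
  lab <- paste(Filter(Negate(is.na),
                      c(x$electrode, x$band, x$condition)), collapse = "/")
  cat(sprintf("<mse_profile>%s avg entropy %.4f over %d scales (m=%d, r=%.2f)\n",
              if (nzchar(lab)) paste0(" ", lab) else "",
              x$avg_entropy, x$params$sf_max, x$params$m, x$params$r))
  invisible(x)
}

#' Band-limited multiscale entropy
#'
#' Zero-phase FIR band-pass of one electrode's series, then [mse_curve()]
#' on the filtered series. The entropy tolerance is taken from the SD of
#' the *filtered* series, so `r` is not dominated by out-of-band variance.
#' `band = NULL` skips filtering (raw-signal profile).
#'
#' @param rec an [recording()].
#' @param electrode channel label.
#' @param band band specification, or `NULL` for the raw signal.
#' @param params an [mse_params()].
#' @param n_samples use only the first `n_samples` samples (default: all).
#' @param condition annotation stored in the profile.
#' @inheritParams mse_curve
#' @return An `mse_profile` annotated with electrode/band/condition.
#' @export
band_limited_mse <- function(rec, electrode, band, params = mse_params(),
                             n_samples = NULL, condition = NA_character_,
                             per_scale_r = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- channel(rec, electrode)
  if (!is.null(n_samples)) {
    if (n_samples > length(x)) stop("n_samples exceeds recording length")
    x <- x[seq_len(n_samples)]
  }
  band_name <- NA_character_
  if (!is.null(band)) {
    band <- as_band(band)
    check_band_vs_fs(band, rec$fs)
    x <- bandpass_filter(x, band, rec$fs)
    band_name <- band$name
  }
  prof <- mse_curve(x, params, per_scale_r = per_scale_r)
  prof$electrode <- if (is.character(electrode)) electrode else rec$labels[electrode]
  prof$band <- band_name
  prof$condition <- condition
  prof
}

#' Classify a task-vs-rest MSE profile change
#'
#' Using the resting profile as the reference: `increased_complexity` when
#' the task profile exceeds rest by more than `tol` at every scale;
#' `toward_regularity` when it is below rest by more than `tol` at every
#' scale; `toward_randomness` when entropy is increased at fine scales
#' (1..k) and decreased beyond some crossover scale k; any other shape is
#' `mixed` (an extension making the classification total).
#'
#' @param task,rest `mse_profile`s with matching parameters.
#' @param tol non-negative tolerance on per-scale differences.
#' @return One of `"increased_complexity"`, `"toward_regularity"`,
#'   `"toward_randomness"`, `"mixed"`.
#' @export
classify_profile <- function(task, rest, tol = 0) {
  stopifnot(inherits(task, "mse_profile"), inherits(rest, "mse_profile"))
  if (!identical(task$params, rest$params)) {
    stop("profiles were computed with different MSE parameters")
  }
  d <- task$entropy_by_scale - rest$entropy_by_scale
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("fewer than 2 defined scales in common")
  if (all(d > tol)) return("increased_complexity")
  if (all(d < -tol)) return("toward_regularity")
  up <- d > tol
  dn <- d < -tol
  for (k in seq_len(length(d) - 1L)) {
    if (all(up[seq_len(k)]) && all(dn[(k + 1L):length(d)])) {
      return("toward_randomness")
    }
  }
  "mixed"
}

#' Percent change of scale-averaged entropy (or any scalar) from rest to task
#'
#' `(task - rest) / rest * 100`.
#'
#' @param task_avg,rest_avg scalars; `rest_avg != 0`.
#' @return Percent change.
#' @export
percent_change <- function(task_avg, rest_avg) {
  if (!is.finite(rest_avg) || rest_avg == 0) {
    stop("rest value must be nonzero and finite")
  }
  (task_avg - rest_avg) / rest_avg * 100
}
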
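#' One-sample t-test with Cohen's d
#'
#' Two-sided `t = (mean - mu0) / (SD/sqrt(n))`, `df = n - 1`, and
#' `d = |mean - mu0| / SD`.
#'
#' @param values finite numeric vector, `n >= 2`, nonzero variance.
#' @param mu0 null mean (default 0).
#' @param label comparison label carried into reports.
#' @return A `test_result`: list with `statistic`, `df`, `p`, `d`, `n`,
#'   `mean`, `label`.
#' @export
one_sample_t <- function(values, mu0 = 0, label = "") {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  s <- stats::sd(values)
  if (s == 0) {
    # all values at the null mean: t = 0 by continuity; off it, undefined
    if (mean(values) == mu0) {
      return(structure(list(statistic = 0, df = length(values) - 1L,
                            p = 1, d = 0, n = length(values),
                            mean = mu0, label = label),
                       class = "test_result"))
    }
    stop("zero variance: t statistic undefined")
  }
  tt <- stats::t.test(values, mu = mu0)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, d = abs(mean(values) - mu0) / s,
                 n = length(values), mean = mean(values), label = label),
            class = "test_result")
}

#' Paired t-test (task minus rest) with Cohen's d
#'
#' A [one_sample_t()] on the differences `task - rest`; positive statistics
#' mean larger task values.
#'
#' @param rest_values,task_values equal-length numeric vectors, `n >= 2`.
#' @param label comparison label.
#' @return A `test_result` on the differences.
#' @export
paired_t <- function(rest_values, task_values, label = "") {
  if (length(rest_values) != length(task_values)) {
    stop("rest and task vectors must have equal length")
  }
  one_sample_t(task_values - rest_values, mu0 = 0, label = label)
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%st(%d) = %.3f, p = %.4g, d = %.3f (mean %.3f, n = %d)\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              x$df, x$statistic, x$p, x$d, x$mean, x$n))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / k`, reported both at full precision and rounded to 3 decimals
#' (the convention of the reported analyses: 0.05 over 12 electrode
#' comparisons prints as 0.004).
#'
#' @param alpha family-wise level.
#' @param k number of comparisons, `>= 1`.
#' @return List with `threshold` (full precision) and `rounded`.
#' @export
bonferroni <- function(alpha = 0.05, k) {
  if (k < 1) stop("k must be >= 1")
  thr <- alpha / k
  list(threshold = thr, rounded = round(thr, 3))
}

#' Regress desynchronization on a complexity or power predictor
#'
#' Ordinary least squares of the C3 desynchronization score on one of three
#' single-predictor models: resting scale-averaged entropy (model 1), task
#' entropy (model 2), or baseline mu power (model 3).
#'
#' @param records subject-level data frame (see [run_cohort()]) with
#'   columns `desync_C3`, `entropy_rest`, `entropy_task`, `mu_power_rest`.
#' @param predictor `"baseline_entropy"`, `"task_entropy"` or
#'   `"baseline_power"`.
#' @return A `regression_result`: list with `coefficients` (estimate, SE,
#'   t, p for intercept and slope), `r_squared`, `rmse` (residual standard
#'   error), `df`, `f`, `f_p`, `predictor`.
#' @export
regress_desync_on_baseline <- function(records,
                                       predictor = c("baseline_entropy",
                                                     "task_entropy",
                                                     "baseline_power")) {
  predictor <- match.arg(predictor)
  col <- switch(predictor,
                baseline_entropy = "entropy_rest",
                task_entropy = "entropy_task",
                baseline_power = "mu_power_rest")
  y <- records$desync_C3
  x <- records[[col]]
  if (is.null(y) || is.null(x)) stop("records lack required columns")
  if (length(y) < 3L) stop("need at least 3 subjects")
  if (stats::sd(x) == 0) stop("constant predictor: regression undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  rownames(co) <- c("intercept", predictor)
  structure(list(coefficients = co, r_squared = sm$r.squared,
                 rmse = sm$sigma, df = fit$df.residual,
                 f = unname(sm$fstatistic[1]),
                 f_p = stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                 sm$fstatistic[3], lower.tail = FALSE),
                 predictor = predictor),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS desync ~ %s: slope %.3f (SE %.3f), R^2 = %.3f, RMSE = %.3f, F(1, %d) = %.3f, p = %.4g\n",
              x$predictor, x$coefficients[2, 1], x$coefficients[2, 2],
              x$r_squared, x$rmse, x$df, x$f, x$f_p))
  invisible(x)
}

#' Pearson correlation of two percent-change series
#'
#' Pearson r with `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, `df = n - 2`
#' (used for the entropy-change vs efficiency-change association).
#'
#' @param entropy_pct_change,ge_pct_change equal-length vectors, `n >= 3`,
#'   each with nonzero variance.
#' @return List with `r`, `t`, `p`, `df`, `n`.
#' @export
corr_change <- function(entropy_pct_change, ge_pct_change) {
  x <- as.numeric(entropy_pct_change); y <- as.numeric(ge_pct_change)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic), p = ct$p.value,
       df = unname(ct$parameter), n = length(x))
}
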
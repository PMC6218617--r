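#' Welch band power
#'
#' Average of Hamming-windowed, overlapping FFT periodograms, integrated
#' over the requested band. The periodogram is normalized as a one-sided
#' power spectral density, so the integrated band power equals the band's
#' contribution to the signal variance: a pure sinusoid of amplitude A
#' inside the band yields `A^2/2` (calibration constant 1). Bins with
#' `low <= f <= high` (both edges inclusive) are summed.
#'
#' @param x single-channel numeric series (µV).
#' @param fs sampling rate (Hz).
#' @param band a [band_definition()], a default band name, or `c(low, high)`.
#' @param window_len window length in seconds (default 1).
#' @param overlap_frac fractional window overlap (default 0.25).
#' @return Band power in µV² (non-negative scalar).
#' @examples
#' x <- 10 * sin(2 * pi * 10 * (0:4999) / 500)
#' band_power(x, 500, "alpha")  # ~ 50 = 10^2/2
#' @export
band_power <- function(x, fs, band, window_len = 1, overlap_frac = 0.25) {
  band <- as_band(band)
  check_band_vs_fs(band, fs)
  nwin <- round(window_len * fs)
  if (length(x) < nwin) {
    stop("segment (", length(x), " samples) shorter than one window (",
         nwin, " samples)")
  }
  step <- max(1L, round(nwin * (1 - overlap_frac)))
  w <- hamming_window(nwin)
  U <- sum(w^2)
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  nhalf <- floor(nwin / 2) + 1L
  freqs <- (seq_len(nhalf) - 1L) * fs / nwin
  sel <- freqs >= band$low & freqs <= band$high
  df <- fs / nwin
  acc <- 0
  for (s in starts) {
    X <- fft(x[s:(s + nwin - 1L)] * w)
    p <- Mod(X[seq_len(nhalf)])^2 / (fs * U)
    # one-sided: double everything except DC (and Nyquist for even nwin)
    dbl <- rep(2, nhalf)
    dbl[1] <- 1
    if (nwin %% 2 == 0) dbl[nhalf] <- 1
    acc <- acc + sum(p[sel] * dbl[sel]) * df
  }
  acc / length(starts)
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Mu/alpha desynchronization score
#'
#' `(ln(task power) - ln(rest power)) / ln(rest power) * 100`. Negative
#' values indicate desynchronization (task power below rest). The formula
#' divides by `ln` of the resting power, so resting power must exceed
#' 1 µV² in the working units; at or below 1 the denominator is zero or
#' negative and the score is undefined/sign-flipped, which is rejected.
#'
#' @param task_power,rest_power band powers in µV²; `task_power > 0`,
#'   `rest_power > 1`.
#' @return Score in percent.
#' @examples
#' desync_score(50, 100)  # ~ -15.05
#' @export
desync_score <- function(task_power, rest_power) {
  if (!is.finite(rest_power) || rest_power <= 1) {
    stop("rest_power must be > 1 uV^2: the score divides by ln(rest_power), ",
         "which is <= 0 for rest_power <= 1")
  }
  if (!is.finite(task_power) || task_power <= 0) {
    stop("task_power must be > 0")
  }
  (log(task_power) - log(rest_power)) / log(rest_power) * 100
}

#' Trial-averaged desynchronization at one electrode
#'
#' Band power is computed per task epoch and averaged over epochs, then a
#' single [desync_score()] is taken against the resting band power.
#'
#' @param epochs_task an `epoch_set` from [extract_epochs()] (task epochs).
#' @param rest resting-state [recording()].
#' @param electrode channel label present in both recordings.
#' @param band band specification (see [band_power()]).
#' @param rest_samples optionally use only the first `rest_samples` samples
#'   of the rest recording (default: all).
#' @param window_len,overlap_frac Welch parameters, see [band_power()].
#' @return A `desync_score` record: list with `electrode`, `value`
#'   (percent), `task_power`, `rest_power`, `n_epochs`.
#' @export
trial_average_desync <- function(epochs_task, rest, electrode, band,
                                 rest_samples = NULL,
                                 window_len = 1, overlap_frac = 0.25) {
  stopifnot(inherits(epochs_task, "epoch_set"), inherits(rest, "eeg_recording"))
  n_ep <- nrow(epochs_task$segments)
  if (n_ep < 1) stop("need at least one task epoch")
  fs <- epochs_task$source$fs
  powers <- vapply(seq_len(n_ep), function(i) {
    band_power(epoch_series(epochs_task, i, electrode), fs, band,
               window_len, overlap_frac)
  }, numeric(1))
  rest_x <- channel(rest, electrode)
  if (!is.null(rest_samples)) rest_x <- rest_x[seq_len(rest_samples)]
  rest_power <- band_power(rest_x, rest$fs, band, window_len, overlap_frac)
  task_power <- mean(powers)
  structure(list(electrode = electrode,
                 value = desync_score(task_power, rest_power),
                 task_power = task_power, rest_power = rest_power,
                 n_epochs = n_ep),
            class = "desync_record")
}

#' @export
print.desync_record <- function(x, ...) {
  cat(sprintf("<desync> %s: %.2f%% (task %.2f / rest %.2f uV^2, %d epochs)\n",
              x$electrode, x$value, x$task_power, x$rest_power, x$n_epochs))
  invisible(x)
}
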
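# Zero-phase FIR band-pass filtering and analytic-signal phase.

#' Default FIR band-pass order
#'
#' Hamming-windowed FIR (>= 50 dB stopband attenuation) with order set by
#' the 3.3/transition-width rule; the transition width is a quarter of the
#' band width, floored at 1 Hz. For short segments the order is capped at
#' `floor((len - 2)/3)` so that zero-phase filtering and edge trimming
#' remain feasible (the cap widens the transition band; documented in the
#' methods vignette).
#'
#' @param band a [band_definition()].
#' @param fs sampling rate (Hz).
#' @param len optional series length imposing the cap.
#' @return Even integer filter order.
#' @export
fir_order <- function(band, fs, len = NULL) {
  tw <- max(1, 0.25 * (band$high - band$low))
  ord <- ceiling(3.3 * fs / tw)
  ord <- max(ord, 8L)
  if (ord %% 2 == 1) ord <- ord + 1L
  # cap (kept even) so that filtfilt + trimming stay feasible on short input
  if (!is.null(len)) ord <- min(ord, 2 * floor((len - 2) / 6))
  as.integer(max(ord, 8L))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-windowed FIR design (`signal::fir1`) applied forward and
#' backward (`signal::filtfilt`), so the passband phase response is zero.
#'
#' @param x numeric series.
#' @param band a [band_definition()] (or name / `c(low, high)`).
#' @param fs sampling rate (Hz).
#' @param order filter order; default [fir_order()].
#' @return Filtered series, same length, with attribute `"order"`.
#' @export
bandpass_filter <- function(x, band, fs, order = NULL) {
  band <- as_band(band)
  check_band_vs_fs(band, fs)
  if (is.null(order)) order <- fir_order(band, fs, len = length(x))
  if (length(x) <= 3 * order) {
    stop("series too short (", length(x), ") for zero-phase filtering at ",
         "order ", order)
  }
  b <- as.numeric(signal::fir1(order, c(band$low, band$high) / (fs / 2),
                               type = "pass"))
  y <- signal::filtfilt(b, 1, as.numeric(x))
  attr(y, "order") <- order
  y
}

# analytic signal via the FFT method (positive frequencies doubled)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Zero-phase band-pass, analytic signal (Hilbert via FFT), then the
#' argument in `(-pi, pi]`. One filter length of samples is trimmed from
#' each end before returning: the analytic-signal edge transient biases
#' phase-locking estimates upward.
#'
#' @param x single-channel numeric series.
#' @param band band specification.
#' @param fs sampling rate (Hz).
#' @param order FIR order (default [fir_order()] capped by the length).
#' @return Phase series in radians, shortened by `2 * order` samples, with
#'   attribute `"trim"` giving the per-end trim.
#' @export
instantaneous_phase <- function(x, band, fs, order = NULL) {
  if (stats::sd(x) == 0) stop("degenerate (constant) signal: phase undefined")
  band <- as_band(band)
  if (is.null(order)) order <- fir_order(band, fs, len = length(x))
  y <- bandpass_filter(x, band, fs, order = order)
  trim <- order
  if (length(y) - 2 * trim < 2) {
    stop("series too short after trimming the filter transient (",
         2 * trim, " samples)")
  }
  ph <- Arg(analytic_signal(as.numeric(y)))
  out <- ph[(trim + 1):(length(ph) - trim)]
  attr(out, "trim") <- trim
  out
}
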
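#' Frequency band definition
#'
#' A named frequency band `[low, high]` in Hz. The conventional EEG bands
#' used throughout the pipeline are provided by [default_bands()].
#'
#' @param name band name, e.g. `"alpha"`.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return A `band_definition` list with elements `name`, `low`, `high`.
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop("band edges must satisfy 0 < low < high (got [", low, ", ", high, "])")
  }
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Conventional EEG frequency bands
#'
#' delta 1-4 Hz, theta 4-8 Hz, alpha (mu over sensorimotor sites) 8-13 Hz,
#' beta 13-30 Hz, gamma 30-60 Hz.
#'
#' @return Named list of [band_definition()] objects.
#' @export
default_bands <- function() {
  list(
    delta = band_definition("delta", 1, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30),
    gamma = band_definition("gamma", 30, 60)
  )
}

# resolve a band given as band_definition, name into a bands list, or c(low, high)
as_band <- function(band, bands = default_bands()) {
  if (inherits(band, "band_definition")) return(band)
  if (is.character(band) && length(band) == 1L) {
    if (!band %in% names(bands)) stop("unknown band name: ", band)
    return(bands[[band]])
  }
  if (is.numeric(band) && length(band) == 2L) {
    return(band_definition("custom", band[1], band[2]))
  }
  stop("band must be a band_definition, a band name, or c(low, high)")
}

check_band_vs_fs <- function(band, fs) {
  if (band$high >= fs / 2) {
    stop("band ", band$name, " [", band$low, ", ", band$high,
         "] Hz exceeds the Nyquist frequency ", fs / 2, " Hz")
  }
  invisible(band)
}
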
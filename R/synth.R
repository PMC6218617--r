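#' Specification of a synthetic EEG recording pair
#'
#' Fully parameterizes the synthetic generator: per-channel, per-condition,
#' per-band oscillation amplitudes, pairwise phase coupling strengths, the
#' 1/f^beta background, and the seed. Identical specs (same seed) reproduce
#' bit-identical recordings.
#'
#' Oscillations are narrowband processes — a sinusoid whose instantaneous
#' frequency drifts slowly inside the band, plus a slow phase random walk —
#' not pure tones, so that band-pass + analytic-signal phase extraction is
#' nondegenerate and uncoupled channels decohere.
#'
#' @param labels channel labels (defines the channel count and order).
#' @param fs sampling rate in Hz; must exceed twice the highest band edge.
#' @param duration_rest,duration_task condition durations in seconds.
#' @param band_amplitudes data frame with columns `channel`, `condition`
#'   (`"rest"`/`"task"`), `band`, `amplitude` (peak amplitude in µV, >= 0).
#'   A band/channel/condition not listed has amplitude 0.
#' @param coupling data frame with columns `source`, `target`, `band`,
#'   `kappa_rest`, `kappa_task`: the target channel's band phase is the
#'   source channel's phase plus von Mises jitter with the condition's
#'   concentration kappa (>= 0; larger = tighter coupling). A channel may be
#'   the target of at most one coupling per band.
#' @param noise_exponent beta of the 1/f^beta background (default 1).
#' @param noise_amplitude standard deviation of the background in µV.
#' @param bands named list of [band_definition()]s the band names refer to.
#' @param seed integer seed; the sole source of randomness.
#' @return A `synth_spec` object.
#' @export
synth_spec <- function(labels = montage_32(), fs = 500,
                       duration_rest = 30, duration_task = 30,
                       band_amplitudes = NULL, coupling = NULL,
                       noise_exponent = 1, noise_amplitude = 7,
                       bands = default_bands(), seed = 1L) {
  if (is.null(band_amplitudes)) {
    band_amplitudes <- data.frame(channel = character(), condition = character(),
                                  band = character(), amplitude = numeric())
  }
  if (is.null(coupling)) {
    coupling <- data.frame(source = character(), target = character(),
                           band = character(), kappa_rest = numeric(),
                           kappa_task = numeric())
  }
  spec <- structure(list(labels = as.character(labels), fs = fs,
                         duration_rest = duration_rest,
                         duration_task = duration_task,
                         band_amplitudes = band_amplitudes,
                         coupling = coupling,
                         noise_exponent = noise_exponent,
                         noise_amplitude = noise_amplitude,
                         bands = bands, seed = as.integer(seed)),
                    class = "synth_spec")
  validate_synth_spec(spec)
}

validate_synth_spec <- function(spec) {
  with(spec, {
    if (anyDuplicated(labels)) stop("duplicated channel labels in spec")
    if (fs <= 0) stop("fs must be > 0")
    if (duration_rest <= 0 || duration_task <= 0) stop("durations must be > 0")
    if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
    if (nrow(band_amplitudes) > 0) {
      if (any(band_amplitudes$amplitude < 0)) stop("amplitudes must be >= 0")
      bad <- setdiff(band_amplitudes$channel, labels)
      if (length(bad)) stop("band_amplitudes names unknown channels: ",
                            paste(unique(bad), collapse = ", "))
      ub <- setdiff(band_amplitudes$band, names(bands))
      if (length(ub)) stop("band_amplitudes names unknown bands: ",
                           paste(unique(ub), collapse = ", "))
      if (!all(band_amplitudes$condition %in% c("rest", "task"))) {
        stop("band_amplitudes$condition must be 'rest' or 'task'")
      }
    }
    if (nrow(coupling) > 0) {
      if (any(coupling$kappa_rest < 0) || any(coupling$kappa_task < 0)) {
        stop("coupling concentrations kappa must be >= 0")
      }
      bad <- setdiff(c(coupling$source, coupling$target), labels)
      if (length(bad)) stop("coupling names unknown channels: ",
                            paste(unique(bad), collapse = ", "))
      dup <- duplicated(coupling[, c("target", "band")])
      if (any(dup)) stop("a channel may be the target of at most one coupling per band")
    }
    used <- unique(band_amplitudes$band)
    for (b in used) check_band_vs_fs(bands[[b]], fs)
  })
  spec
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf("<synth_spec> %d channels @ %g Hz, rest %gs / task %gs, 1/f^%g noise sd %g uV, seed %d\n",
              length(x$labels), x$fs, x$duration_rest, x$duration_task,
              x$noise_exponent, x$noise_amplitude, x$seed))
  cat(sprintf("  %d amplitude entries, %d coupled pairs\n",
              nrow(x$band_amplitudes), nrow(x$coupling)))
  invisible(x)
}

#' Serialize / load a synth_spec as YAML
#' @param spec a [synth_spec()].
#' @param path file path.
#' @return `read_synth_spec` returns the reconstructed `synth_spec`.
#' @export
write_synth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  out <- unclass(spec)
  out$band_amplitudes <- lapply(seq_len(nrow(spec$band_amplitudes)),
                                function(i) as.list(spec$band_amplitudes[i, ]))
  out$coupling <- lapply(seq_len(nrow(spec$coupling)),
                         function(i) as.list(spec$coupling[i, ]))
  out$bands <- lapply(spec$bands, function(b) list(low = b$low, high = b$high))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  amp <- if (length(raw$band_amplitudes)) {
    do.call(rbind, lapply(raw$band_amplitudes, as.data.frame))
  } else NULL
  cpl <- if (length(raw$coupling)) {
    do.call(rbind, lapply(raw$coupling, as.data.frame))
  } else NULL
  bands <- mapply(function(nm, b) band_definition(nm, b$low, b$high),
                  names(raw$bands), raw$bands, SIMPLIFY = FALSE)
  synth_spec(labels = raw$labels, fs = raw$fs,
             duration_rest = raw$duration_rest,
             duration_task = raw$duration_task,
             band_amplitudes = amp, coupling = cpl,
             noise_exponent = raw$noise_exponent,
             noise_amplitude = raw$noise_amplitude,
             bands = bands, seed = raw$seed)
}

#' Von Mises random deviates
#'
#' Best & Fisher (1979) rejection sampler; `kappa = 0` reduces to the
#' uniform distribution on `(-pi, pi]`. Mean resultant length of the
#' distribution is `I1(kappa)/I0(kappa)`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, `>= 0` (`Inf` allowed: point mass at `mu`).
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (is.infinite(kappa)) return(wrap_pi(rep(mu, n)))
  if (kappa < 1e-8) return(wrap_pi(runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling((n - length(out)) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1)))
  }
  wrap_pi(out[seq_len(n)] + mu)
}

# wrap angles to (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' 1/f^beta background noise
#'
#' Spectral shaping of white Gaussian noise: Fourier amplitudes scaled by
#' `f^(-beta/2)` (DC removed), then rescaled to the requested standard
#' deviation.
#'
#' @param n number of samples.
#' @param beta spectral exponent (1 = pink).
#' @param sd target standard deviation (µV).
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, beta = 1, sd = 1) {
  if (sd == 0) return(numeric(n))
  w <- rnorm(n)
  X <- fft(w)
  f <- fft_freqs(n, 1)           # unit fs; only the shape matters
  shape <- c(0, abs(f[-1])^(-beta / 2))
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

# two-sided FFT bin frequencies for length n at rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Fraction of 1/f^beta noise variance inside a band
#'
#' Exact on the discrete Fourier grid the generator synthesizes on; used to
#' account for the background's in-band power when translating a target
#' desynchronization into task oscillation amplitudes.
#'
#' @param n series length in samples.
#' @param fs sampling rate (Hz).
#' @param beta spectral exponent.
#' @param band a [band_definition()].
#' @return Fraction in `[0, 1]`.
#' @export
pink_band_fraction <- function(n, fs, beta, band) {
  f <- abs(fft_freqs(n, fs))
  pos <- f > 0
  w <- f[pos]^(-beta)
  sum(w[f[pos] >= band$low & f[pos] <= band$high]) / sum(w)
}

# narrowband phase walk: instantaneous frequency drifts sinusoidally inside
# the band around a randomized center, plus a slow phase random walk
phase_walk <- function(n, band, fs, diffusion = 0.03) {
  width <- band$high - band$low
  f0 <- runif(1, band$low + 0.35 * width, band$high - 0.35 * width)
  drift_rate <- runif(1, 0.1, 0.3)           # Hz, slow
  drift_phase <- runif(1, 0, 2 * pi)
  t <- (0:(n - 1)) / fs
  finst <- f0 + 0.15 * width * sin(2 * pi * drift_rate * t + drift_phase)
  2 * pi * cumsum(finst) / fs + cumsum(rnorm(n, 0, diffusion)) +
    runif(1, 0, 2 * pi)
}

# piecewise-constant von Mises phase offsets (held hold_s seconds) so the
# injected jitter survives narrowband filtering in the measurement chain
held_vonmises <- function(n, kappa, fs, hold_s = 0.2) {
  hold <- max(1L, round(hold_s * fs))
  k <- ceiling(n / hold)
  rep(rvonmises(k, 0, kappa), each = hold)[seq_len(n)]
}

#' Generate a rest/task pair of synthetic EEG recordings
#'
#' Each channel is the sum over bands of `amplitude * sin(phase)` plus
#' 1/f^beta background noise. Band phases follow independent narrowband
#' walks per channel; a coupled target channel instead reuses its source's
#' walk plus von Mises jitter of the condition's concentration kappa. The
#' two conditions are generated with independent noise; only the spec'd
#' amplitudes and coupling strengths differ.
#'
#' @param spec a [synth_spec()].
#' @return List with elements `rest` and `task`, each an [recording()].
#' @examples
#' amp <- data.frame(channel = "C3", condition = c("rest", "task"),
#'                   band = "alpha", amplitude = c(10, 5))
#' recs <- gen_recording(synth_spec(labels = c("C3", "C4"), duration_rest = 4,
#'                                  duration_task = 4, band_amplitudes = amp,
#'                                  noise_amplitude = 1, seed = 7))
#' recs$rest
#' @export
gen_recording <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  validate_synth_spec(spec)
  set.seed(spec$seed)
  out <- list()
  for (cond in c("rest", "task")) {
    dur <- if (cond == "rest") spec$duration_rest else spec$duration_task
    n <- round(dur * spec$fs)
    data <- matrix(0, length(spec$labels), n)
    rownames(data) <- spec$labels
    amps <- spec$band_amplitudes[spec$band_amplitudes$condition == cond, ,
                                 drop = FALSE]
    used_bands <- sort(unique(c(amps$band, spec$coupling$band)))
    for (bname in used_bands) {
      band <- spec$bands[[bname]]
      cpl <- spec$coupling[spec$coupling$band == bname, , drop = FALSE]
      kap <- if (cond == "rest") cpl$kappa_rest else cpl$kappa_task
      phases <- matrix(NA_real_, length(spec$labels), n,
                       dimnames = list(spec$labels, NULL))
      # sources first (label order), then coupled targets
      for (ch in setdiff(spec$labels, cpl$target)) {
        phases[ch, ] <- phase_walk(n, band, spec$fs)
      }
      if (nrow(cpl) > 0) {
        for (k in seq_len(nrow(cpl))) {
          if (anyNA(phases[cpl$source[k], ])) {
            stop("coupling chains are not supported: source ", cpl$source[k],
                 " is itself a coupling target in band ", bname)
          }
          phases[cpl$target[k], ] <- phases[cpl$source[k], ] +
            held_vonmises(n, kap[k], spec$fs)
        }
      }
      for (ch in spec$labels) {
        a <- amps$amplitude[amps$channel == ch & amps$band == bname]
        if (length(a) && a[1] > 0) {
          data[ch, ] <- data[ch, ] + a[1] * sin(phases[ch, ])
        }
      }
    }
    if (spec$noise_amplitude > 0) {
      for (ch in seq_along(spec$labels)) {
        data[ch, ] <- data[ch, ] +
          pink_noise(n, spec$noise_exponent, spec$noise_amplitude)
      }
    }
    out[[cond]] <- recording(data, spec$fs, spec$labels)
  }
  out
}

#' Task/rest power ratio that realizes a target desynchronization
#'
#' Inverts the desynchronization formula: a score of `D` percent against a
#' resting power `P` requires `P_task / P_rest = P^(D/100)`. Feeding the
#' scaled power back through [desync_score()] returns `D` exactly.
#'
#' @param target_desync desynchronization score in percent (negative =
#'   suppression).
#' @param rest_power resting band power in µV², must exceed 1 (the formula
#'   divides by `ln` rest power).
#' @return The ratio `P_task / P_rest`.
#' @examples
#' power_ratio_for_desync(-15.0515, 100)  # ~ 0.5
#' @export
power_ratio_for_desync <- function(target_desync, rest_power) {
  if (!is.finite(rest_power) || rest_power <= 1) {
    stop("rest_power must be > 1 uV^2: ln(rest_power) is the formula's ",
         "denominator and must be positive")
  }
  rest_power^(target_desync / 100)
}

#' Generate a pair of von Mises-coupled phase series
#'
#' `phase_b = phase_a + vonMises(0, kappa)` with i.i.d. jitter; the expected
#' phase-locking value between the two series is `I1(kappa)/I0(kappa)`
#' (ratio of modified Bessel functions; 1 as `kappa -> Inf`, 0 at
#' `kappa = 0`).
#'
#' @param kappa concentration of the jitter, `>= 0` (`Inf` = zero noise).
#' @param n number of samples.
#' @param seed integer seed.
#' @return List with numeric vectors `phase_a`, `phase_b` in `(-pi, pi]`.
#' @export
gen_coupled_phases <- function(kappa, n, seed = 1L) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  phase_a <- cumsum(rnorm(n, 0, 0.1)) + runif(1, 0, 2 * pi)
  noise <- if (is.infinite(kappa)) numeric(n) else rvonmises(n, 0, kappa)
  list(phase_a = wrap_pi(phase_a), phase_b = wrap_pi(phase_a + noise))
}
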
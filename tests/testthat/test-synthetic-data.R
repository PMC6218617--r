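# Synthetic EEG generator: determinism, spectral ground truth, coupling
# ground truth, and the desynchronization inverse mapping.

zero_spec <- function() {
  synth_spec(labels = c("C3", "C4"), fs = 250, duration_rest = 2,
             duration_task = 2, noise_amplitude = 0, seed = 3,
             bands = default_bands()[c("alpha", "beta")])
}

test_that("all-zero amplitudes and zero noise give an all-zero recording", {
  recs <- gen_recording(zero_spec())
  expect_true(all(recs$rest$data == 0))
  expect_true(all(recs$task$data == 0))
})

test_that("the same spec reproduces bit-identical recordings", {
  amp <- data.frame(channel = "C3", condition = c("rest", "task"),
                    band = "alpha", amplitude = c(10, 5))
  spec <- synth_spec(labels = c("C3", "C4"), fs = 500, duration_rest = 3,
                     duration_task = 3, band_amplitudes = amp,
                     noise_amplitude = 4, seed = 42)
  a <- gen_recording(spec)
  b <- gen_recording(spec)
  expect_identical(a$rest$data, b$rest$data)
  expect_identical(a$task$data, b$task$data)
})

test_that("spec validation rejects bad amplitudes, kappas and band edges", {
  expect_error(synth_spec(labels = c("C3", "C3")), "duplicated")
  amp <- data.frame(channel = "C3", condition = "rest", band = "alpha",
                    amplitude = -1)
  expect_error(synth_spec(labels = "C3", band_amplitudes = amp), ">= 0")
  cpl <- data.frame(source = "C3", target = "C4", band = "alpha",
                    kappa_rest = -2, kappa_task = 1)
  expect_error(synth_spec(labels = c("C3", "C4"), coupling = cpl), "kappa")
  # gamma reaches 60 Hz: a 100 Hz rate violates Nyquist for that band
  amp2 <- data.frame(channel = "C3", condition = "rest", band = "gamma",
                     amplitude = 1)
  expect_error(synth_spec(labels = "C3", fs = 100, band_amplitudes = amp2),
               "Nyquist")
})

test_that("narrowband power scales as amplitude squared", {
  # noiseless, long: halved task amplitude -> quarter task power
  amp <- data.frame(channel = "C3", condition = c("rest", "task"),
                    band = "alpha", amplitude = c(8, 4))
  spec <- synth_spec(labels = "C3", fs = 500, duration_rest = 60,
                     duration_task = 60, band_amplitudes = amp,
                     noise_amplitude = 0, seed = 9)
  recs <- gen_recording(spec)
  p_rest <- band_power(channel(recs$rest, "C3"), 500, "alpha")
  p_task <- band_power(channel(recs$task, "C3"), 500, "alpha")
  expect_equal(p_rest, 8^2 / 2, tolerance = 0.01)
  expect_equal(p_task / p_rest, 0.25, tolerance = 0.01)
})

test_that("power_ratio_for_desync inverts the desynchronization score", {
  expect_identical(power_ratio_for_desync(0, 37), 1)
  # round trip through the score at the published-style operating point
  for (D in c(-40, -15.0515, -5, 10)) {
    ratio <- power_ratio_for_desync(D, 100)
    expect_equal(desync_score(100 * ratio, 100), D, tolerance = 1e-12)
  }
  expect_equal(power_ratio_for_desync(-15.0515, 100), 0.5, tolerance = 1e-4)
  expect_equal(power_ratio_for_desync(-100, exp(1)), exp(-1))
  expect_error(power_ratio_for_desync(-10, 1), "> 1")
  expect_error(power_ratio_for_desync(-10, 0.5), "> 1")
})

test_that("von Mises sampler matches the Bessel-ratio resultant length", {
  set.seed(7)
  for (kappa in c(0.5, 2, 8)) {
    th <- rvonmises(20000, 0, kappa)
    expect_equal(Mod(mean(exp(1i * th))),
                 besselI(kappa, 1) / besselI(kappa, 0), tolerance = 0.02)
  }
  expect_true(all(abs(rvonmises(1000, 0, 5)) <= pi))
})

test_that("coupled phases realize the expected phase-locking value", {
  p <- gen_coupled_phases(Inf, 500, seed = 1)
  expect_equal(rpc(p$phase_a, p$phase_b), 1)
  p0 <- gen_coupled_phases(0, 1e4, seed = 1)
  expect_lt(rpc(p0$phase_a, p0$phase_b), 0.05)
  p2 <- gen_coupled_phases(2, 2e4, seed = 1)
  expect_equal(rpc(p2$phase_a, p2$phase_b),
               besselI(2, 1) / besselI(2, 0), tolerance = 0.02)
  # confidence shrinks with n: estimates approach the Bessel ratio
  target <- besselI(2, 1) / besselI(2, 0)
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    p <- gen_coupled_phases(2, n, seed = 5)
    abs(rpc(p$phase_a, p$phase_b) - target)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lt(errs[3], errs[1])
})

test_that("background noise follows a 1/f spectral slope", {
  set.seed(2)
  x <- pink_noise(2^14, beta = 1, sd = 5)
  expect_equal(sd(x), 5, tolerance = 1e-6)
  p <- rowMeans(replicate(6, {
    y <- pink_noise(2^14, beta = 1, sd = 5)
    vapply(list(c(1, 2), c(4, 8), c(16, 32), c(60, 120)),
           function(b) band_power(y, 256, b), numeric(1))
  }))
  slope <- coef(lm(log(p) ~ log(c(1.5, 6, 24, 90))))[2]
  # octave-band power of 1/f noise is flat per octave => integrated band
  # power grows ~ log; slope of log-power vs log-frequency near 0, and
  # clearly above the -1 of per-Hz density and below white noise (+1)
  expect_lt(abs(slope), 0.35)
})

test_that("a synth_spec survives the YAML round trip", {
  amp <- data.frame(channel = "C3", condition = c("rest", "task"),
                    band = "alpha", amplitude = c(10, 5))
  cpl <- data.frame(source = "C3", target = "C4", band = "alpha",
                    kappa_rest = 4, kappa_task = 1)
  spec <- synth_spec(labels = c("C3", "C4"), duration_rest = 2,
                     duration_task = 2, band_amplitudes = amp,
                     coupling = cpl, seed = 77)
  path <- withr::local_tempfile(fileext = ".yml")
  write_synth_spec(spec, path)
  spec2 <- read_synth_spec(path)
  expect_identical(gen_recording(spec)$rest$data,
                   gen_recording(spec2)$rest$data)
})
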
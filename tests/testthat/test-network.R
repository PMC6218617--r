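# Phase extraction, phase-locking weights, and the weighted graph metrics
# against brute-force oracles.

test_that("phase of a band-centered sinusoid advances linearly", {
  fs <- 500
  x <- sin(2 * pi * 10.5 * (0:4999) / fs)
  ph <- instantaneous_phase(x, "alpha", fs)
  inc <- diff(ph)
  inc[inc < -pi] <- inc[inc < -pi] + 2 * pi  # unwrap
  expect_lt(max(abs(inc - 2 * pi * 10.5 / fs)), 1e-3)
})

test_that("negating a signal shifts its phase by pi", {
  fs <- 500
  set.seed(41)
  x <- sin(2 * pi * 10 * (0:2999) / fs) + 0.1 * rnorm(3000)
  p1 <- instantaneous_phase(x, "alpha", fs)
  p2 <- instantaneous_phase(-x, "alpha", fs)
  d <- (p1 - p2) %% (2 * pi)
  expect_lt(max(abs(d - pi)), 1e-6)
})

test_that("degenerate signals are rejected by phase extraction", {
  expect_error(instantaneous_phase(rep(2, 1000), "alpha", 500), "degenerate")
  expect_error(instantaneous_phase(rnorm(20), "alpha", 500), "too short")
})

test_that("rpc is 1 for constant lag, ~0 for a symmetric phase grid", {
  ph <- seq(-pi, pi, length.out = 1001)[-1]
  expect_equal(rpc(ph, ph + 0.7), 1, tolerance = 1e-12)
  expect_lt(rpc(ph, numeric(1000)), 1e-12)
  expect_error(rpc(1:5, 1:4), "mismatch")
})

test_that("rpc lies in [0,1] and ignores common phase offsets", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(200, -pi, pi)
    b <- a + rvonmises(200, 0, runif(1, 0, 5))
    w <- rpc(a, b)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_equal(rpc(a + 1.3, b + 1.3), w, tolerance = 1e-12)
  }
})

test_that("the entropy-based rPC variant ranks coupling like the PLV", {
  set.seed(43)
  a <- runif(5000, -pi, pi)
  strong <- rpc(a, a + rvonmises(5000, 0, 8), method = "entropy")
  weak <- rpc(a, a + rvonmises(5000, 0, 0.2), method = "entropy")
  expect_gt(strong, weak)
  expect_gte(weak, 0); expect_lte(strong, 1)
})

test_that("build_network returns a valid fully connected weighted graph", {
  cpl <- data.frame(source = "C3", target = "C4", band = "alpha",
                    kappa_rest = 8, kappa_task = 8)
  amp <- do.call(rbind, lapply(c("C3", "Cz", "C4", "Pz"), function(ch)
    data.frame(channel = ch, condition = c("rest", "task"), band = "alpha",
               amplitude = 10)))
  spec <- synth_spec(labels = c("C3", "Cz", "C4", "Pz"), fs = 500,
                     duration_rest = 4, duration_task = 4,
                     band_amplitudes = amp, coupling = cpl,
                     noise_amplitude = 2, seed = 55)
  recs <- gen_recording(spec)
  g <- build_network(recs$rest, "alpha", segment = c(0L, 1000L),
                     condition = "rest")
  expect_identical(g$W, t(g$W))
  expect_true(all(diag(g$W) == 0))
  expect_true(all(g$W >= 0 & g$W <= 1))
  off <- g$W[upper.tri(g$W)]
  expect_length(off, choose(4, 2))
  # the one strongly coupled pair carries the largest weight
  expect_equal(max(off), g$W["C3", "C4"])
})

test_that("identical channels get weight 1; flat channels are named in errors", {
  x <- sin(2 * pi * 10 * (0:1999) / 500) + 0.05 * rnorm(2000)
  rec <- recording(rbind(x, x, rnorm(2000)), 500, c("C3", "C4", "Pz"))
  g <- build_network(rec, "alpha")
  expect_equal(g$W["C3", "C4"], 1, tolerance = 1e-9)
  bad <- recording(rbind(x, 0 * x), 500, c("C3", "Flat"))
  expect_error(build_network(bad, "alpha"), "Flat")
})

test_that("clustering coefficient matches its closed forms and the oracle", {
  W1 <- matrix(1, 6, 6); diag(W1) <- 0
  g1 <- connectivity_graph(W1)
  expect_equal(unname(clustering_coefficient(g1)), rep(1, 6))
  expect_equal(aver_cc(g1), 1)

  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.8
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.2
  g <- connectivity_graph(W)
  cc1 <- clustering_coefficient(g, 1)
  expect_equal(cc1, 2 * (0.8 * 0.5 * 0.2)^(1 / 3) / (1.3 * 0.3))
  expect_equal(cc1, cc_oracle(W, 1))

  # a zero-weight edge annihilates its triangle
  W0 <- W; W0[2, 3] <- W0[3, 2] <- 0
  expect_equal(clustering_coefficient(connectivity_graph(W0), 1), 0)
})

test_that("isolated nodes have undefined CC and are excluded from aver_cc", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.8
  W[2, 3] <- W[3, 2] <- 0.7
  g <- connectivity_graph(W)
  cc <- clustering_coefficient(g)
  expect_true(is.na(cc[4]))
  expect_message(m <- aver_cc(g), "excluded")
  expect_equal(m, mean(cc[1:3]))
})

test_that("shortest lengths prefer strong detours over weak direct edges", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.5
  g <- connectivity_graph(W)
  D <- shortest_lengths(g)
  expect_equal(D[1, 3], 2)   # direct edge: detour would cost 1 + 2 = 3
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_equal(global_efficiency(g), 2 * (1 + 0.5 + 0.5) / (3 * 2))

  # absent direct edge: path composes through the intermediate
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 1
  W2[2, 3] <- W2[3, 2] <- 1
  D2 <- shortest_lengths(connectivity_graph(W2))
  expect_equal(D2[1, 3], 2)
})

test_that("direct edges bound the shortest path length", {
  set.seed(44)
  for (i in 1:10) {
    W <- random_weight_matrix(7)
    g <- connectivity_graph(W)
    D <- shortest_lengths(g)
    pos <- W > 0
    expect_true(all(D[pos] <= 1 / W[pos] + 1e-12))
  }
})

test_that("CC and GE agree with brute-force enumeration on random graphs", {
  set.seed(45)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    W <- random_weight_matrix(n, p_edge = runif(1, 0.4, 1))
    g <- connectivity_graph(W)
    cc <- suppressMessages(clustering_coefficient(g))
    for (j in seq_len(n)) {
      o <- cc_oracle(W, j)
      if (is.na(o)) expect_true(is.na(cc[j])) else expect_equal(cc[[j]], o)
    }
    expect_equal(global_efficiency(g), ge_oracle(W), tolerance = 1e-10)
  }
})

test_that("GE is monotone in edge weights and invariant to relabeling", {
  set.seed(46)
  for (i in 1:10) {
    W <- random_weight_matrix(6)
    g <- connectivity_graph(W)
    ge0 <- global_efficiency(g)
    idx <- which(upper.tri(W), arr.ind = TRUE)
    k <- idx[sample(nrow(idx), 1), ]
    W2 <- W
    W2[k[1], k[2]] <- W2[k[2], k[1]] <- min(1, W[k[1], k[2]] + runif(1, 0, 0.5))
    expect_gte(global_efficiency(connectivity_graph(W2)) + 1e-12, ge0)
    perm <- sample(6)
    gp <- connectivity_graph(W[perm, perm])
    expect_equal(global_efficiency(gp), ge0)
    expect_equal(suppressMessages(aver_cc(gp)), suppressMessages(aver_cc(g)))
  }
})

test_that("degenerate efficiencies behave at the boundaries", {
  g0 <- connectivity_graph(matrix(0, 5, 5))
  expect_equal(global_efficiency(g0), 0)
  expect_error(aver_cc(g0), "undefined")
  expect_equal(percent_change_ge(0.5, 0.5), 0)
  expect_equal(percent_change_ge(0.4, 0.5), -20)
  expect_error(percent_change_ge(0.4, 0), "> 0")
})

test_that("weakened coupling lowers global efficiency in the generator", {
  labs <- c("C3", "Cz", "C4", "F3", "Pz")
  cpl <- data.frame(source = "Cz", target = c("C3", "C4", "F3", "Pz"),
                    band = "alpha", kappa_rest = 4, kappa_task = 1)
  amp <- do.call(rbind, lapply(labs, function(ch)
    data.frame(channel = ch, condition = c("rest", "task"), band = "alpha",
               amplitude = 10)))
  spec <- synth_spec(labels = labs, fs = 500, duration_rest = 4,
                     duration_task = 4, band_amplitudes = amp,
                     coupling = cpl, noise_amplitude = 2, seed = 66)
  recs <- gen_recording(spec)
  ge_r <- global_efficiency(build_network(recs$rest, "alpha",
                                          segment = c(0L, 1000L)))
  ge_t <- global_efficiency(build_network(recs$task, "alpha",
                                          segment = c(0L, 1000L)))
  expect_lt(percent_change_ge(ge_t, ge_r), 0)
})
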
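# Independent brute-force oracles, deliberately naive: exhaustive template
# counting for sample entropy, triple-loop triangle sums for the clustering
# coefficient, and depth-first enumeration of simple paths for shortest
# weighted path lengths. These share no code with the package
# implementations they check.

sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) NA_real_ else -log(A / B)
}

cc_oracle <- function(W, j) {
  n <- nrow(W)
  num <- 0
  for (i in seq_len(n)) {
    for (m in seq_len(n)) {
      if (i != j && m != j && i != m) {
        num <- num + (W[i, j] * W[i, m] * W[j, m])^(1 / 3)
      }
    }
  }
  k <- sum(W[, j])
  if (k * (k - 1) <= 0) return(NA_real_)
  num / (k * (k - 1))
}

# all-pairs shortest lengths by DFS over simple paths (branch-and-bound:
# extensions of a path already no shorter than the best known length for
# the node it reaches cannot improve, since lengths are non-negative)
shortest_oracle <- function(L) {
  n <- nrow(L)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    best <- rep(Inf, n)
    best[s] <- 0
    dfs <- function(node, visited, len) {
      for (nb in seq_len(n)) {
        if (!visited[nb] && is.finite(L[node, nb])) {
          nl <- len + L[node, nb]
          if (nl < best[nb]) {
            best[nb] <<- nl
            v <- visited; v[nb] <- TRUE
            dfs(nb, v, nl)
          }
        }
      }
    }
    vis <- rep(FALSE, n); vis[s] <- TRUE
    dfs(s, vis, 0)
    D[s, ] <- best
  }
  D
}

ge_oracle <- function(W, f = function(w) 1 / w) {
  L <- matrix(Inf, nrow(W), ncol(W))
  L[W > 0] <- f(W[W > 0])
  D <- shortest_oracle(L)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (nrow(W) * (nrow(W) - 1))
}

# random symmetric weight matrix in [0, 1], zero diagonal, some absent edges
random_weight_matrix <- function(n, p_edge = 0.8) {
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1)
    }
  }
  W
}

# assorted short series for entropy oracle sweeps
random_series <- function(len, kind) {
  switch(kind,
         white = rnorm(len),
         ar = as.numeric(stats::arima.sim(list(ar = 0.8), len)),
         tone = sin(2 * pi * 0.05 * seq_len(len)) + 0.3 * rnorm(len),
         coarse = round(rnorm(len), 1))  # many ties: exercises boundary cases
}
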
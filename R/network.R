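#' Phase-locking value between two phase series
#'
#' Modulus of the circular mean of `exp(1i * (phase_a - phase_b))` — the
#' phase-locking index used as the respective phase coherence (rPC): 1 for
#' a constant lag, tending to 0 for independent phases. Invariant under
#' adding a constant to either series. An entropy-of-phase-difference
#' variant (normalized Shannon index over binned phase differences) is
#' available via `method = "entropy"`.
#'
#' @param phase_a,phase_b phase series in radians, equal length `>= 2`.
#' @param method `"plv"` (default) or `"entropy"`.
#' @param n_bins histogram bins for the entropy index (default 16).
#' @return Coherence weight in `[0, 1]`.
#' @export
rpc <- function(phase_a, phase_b, method = c("plv", "entropy"), n_bins = 16L) {
  method <- match.arg(method)
  if (length(phase_a) != length(phase_b)) {
    stop("phase series length mismatch: ", length(phase_a), " vs ",
         length(phase_b))
  }
  if (length(phase_a) < 2L) stop("need at least 2 samples")
  d <- wrap_pi(phase_a - phase_b)
  if (method == "plv") {
    return(min(1, Mod(mean(exp(1i * d)))))
  }
  p <- tabulate(findInterval(d, seq(-pi, pi, length.out = n_bins + 1L),
                             rightmost.closed = TRUE), n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  h <- -sum(p * log(p))
  (log(n_bins) - h) / log(n_bins)
}

#' Build a weighted phase-coherence network
#'
#' Band-limits every channel over the given segment, extracts instantaneous
#' phases, and fills a symmetric matrix of pairwise [rpc()] weights: an
#' undirected, weighted, fully connected graph with electrodes as nodes.
#'
#' @param rec an [recording()].
#' @param band band specification.
#' @param segment `c(onset, length)` in samples, 0-based half-open; default
#'   the whole recording.
#' @param condition annotation stored on the graph.
#' @param method rPC variant, see [rpc()].
#' @return A `connectivity_graph`: list with `n`, `labels`, `W` (symmetric,
#'   zero diagonal, weights in `[0, 1]`), `band`, `condition`.
#' @export
build_network <- function(rec, band, segment = NULL, condition = NA_character_,
                          method = c("plv", "entropy")) {
  stopifnot(inherits(rec, "eeg_recording"))
  method <- match.arg(method)
  band <- as_band(band)
  if (is.null(segment)) segment <- c(0L, n_samples(rec))
  idx <- (segment[1] + 1L):(segment[1] + segment[2])
  if (segment[1] < 0 || max(idx) > n_samples(rec)) stop("segment out of bounds")
  n <- length(rec$labels)
  phases <- vector("list", n)
  for (i in seq_len(n)) {
    phases[[i]] <- tryCatch(
      instantaneous_phase(rec$data[i, idx], band, rec$fs),
      error = function(e) {
        stop("channel ", rec$labels[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  W <- matrix(0, n, n, dimnames = list(rec$labels, rec$labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      W[i, j] <- W[j, i] <- rpc(phases[[i]], phases[[j]], method = method)
    }
  }
  structure(list(n = n, labels = rec$labels, W = W, band = band$name,
                 condition = condition),
            class = "connectivity_graph")
}

#' Construct a connectivity graph from a weight matrix
#'
#' @param W symmetric matrix with weights in `[0, 1]`, zero diagonal.
#' @param labels node labels (default from `W`'s dimnames or `V1..Vn`).
#' @param band,condition annotations.
#' @return A `connectivity_graph`.
#' @export
connectivity_graph <- function(W, labels = NULL, band = NA_character_,
                               condition = NA_character_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (any(W < 0) || any(W > 1)) stop("weights must lie in [0, 1]")
  W <- (W + t(W)) / 2
  if (is.null(labels)) {
    labels <- rownames(W)
    if (is.null(labels)) labels <- paste0("V", seq_len(nrow(W)))
  }
  dimnames(W) <- list(labels, labels)
  structure(list(n = nrow(W), labels = labels, W = W, band = band,
                 condition = condition),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> %d nodes (%s%s), mean weight %.3f\n",
              x$n, if (is.na(x$band)) "?" else x$band,
              if (is.na(x$condition)) "" else paste0(", ", x$condition),
              mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

node_index <- function(g, j) {
  if (is.character(j)) {
    k <- match(j, g$labels)
    if (is.na(k)) stop("unknown node label: ", j)
    return(k)
  }
  as.integer(j)
}

#' Weighted clustering coefficient
#'
#' For node j, the sum over ordered neighbor pairs (i, m) of the geometric
#' mean of the triangle's edge weights, `(w_ij w_im w_jm)^(1/3)`, divided
#' by `k_j (k_j - 1)` with `k_j = sum_i w_ij` the *weighted* degree — the
#' formula as printed in the source analysis. Because the normalization
#' uses the weighted degree rather than the neighbor count, values can
#' exceed 1. The strict standard variant (denominator from the count of
#' nonzero-weight neighbors) is available with `degree = "count"`.
#' Undefined (`NA`) when `k_j (k_j - 1) <= 0`.
#'
#' @param g a `connectivity_graph` with `n >= 3`.
#' @param j node label or index; `NULL` (default) returns all nodes.
#' @param degree `"weighted"` (as printed) or `"count"`.
#' @return Named numeric vector of CC values (or a scalar for a single `j`).
#' @export
clustering_coefficient <- function(g, j = NULL,
                                   degree = c("weighted", "count")) {
  stopifnot(inherits(g, "connectivity_graph"))
  degree <- match.arg(degree)
  if (g$n < 3L) stop("clustering coefficient needs at least 3 nodes")
  W3 <- g$W^(1 / 3)
  num <- diag(W3 %*% W3 %*% W3)  # sum over ordered pairs of cube-root products
  k <- if (degree == "weighted") colSums(g$W) else colSums(g$W > 0)
  den <- k * (k - 1)
  cc <- ifelse(den > 0, num / den, NA_real_)
  names(cc) <- g$labels
  if (is.null(j)) cc else cc[[node_index(g, j)]]
}

#' Network-average clustering coefficient
#'
#' Arithmetic mean of the defined per-node [clustering_coefficient()]s;
#' undefined nodes are excluded with a message.
#'
#' @inheritParams clustering_coefficient
#' @return Scalar mean CC.
#' @export
aver_cc <- function(g, degree = c("weighted", "count")) {
  cc <- clustering_coefficient(g, degree = match.arg(degree))
  if (all(is.na(cc))) stop("clustering coefficient undefined at every node")
  if (anyNA(cc)) {
    message(sum(is.na(cc)), " nodes with undefined CC excluded from aver_CC")
  }
  mean(cc, na.rm = TRUE)
}

#' All-pairs shortest weighted path lengths
#'
#' Edge lengths are `f(w)` (default the inverse map, `1/w`); zero-weight
#' edges have infinite length (absent). Pairs with no connecting path get
#' `Inf`, which [global_efficiency()] treats as a zero contribution.
#'
#' @param g a `connectivity_graph`.
#' @param f weight-to-length map (default `function(w) 1/w`).
#' @return Symmetric matrix `D` with `d_ii = 0` and
#'   `d_ij <= f(w_ij)` for every direct edge.
#' @export
shortest_lengths <- function(g, f = function(w) 1 / w) {
  stopifnot(inherits(g, "connectivity_graph"))
  L <- matrix(Inf, g$n, g$n)
  pos <- g$W > 0
  L[pos] <- f(g$W[pos])
  if (any(L[pos] < 0)) stop("f must map weights to non-negative lengths")
  A <- ifelse(is.finite(L), L, 0)
  gr <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  D <- igraph::distances(gr, weights = igraph::E(gr)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- list(g$labels, g$labels)
  D
}

#' Global efficiency
#'
#' `GE = 1/(N(N-1)) * sum_{i != j} 1/d_ij` over ordered pairs, with
#' `1/Inf = 0` — the formulation that tolerates isolated points (a fully
#' disconnected graph has GE 0; a uniform complete unit-weight graph has
#' GE 1 under the inverse map).
#'
#' @inheritParams shortest_lengths
#' @return Scalar efficiency `>= 0`.
#' @export
global_efficiency <- function(g, f = function(w) 1 / w) {
  stopifnot(inherits(g, "connectivity_graph"))
  if (g$n < 2L) stop("global efficiency needs at least 2 nodes")
  D <- shortest_lengths(g, f)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (g$n * (g$n - 1))
}

#' Percent change in global efficiency from rest to task
#'
#' `(task - rest)/rest * 100`; requires `rest_ge > 0`.
#'
#' @param task_ge,rest_ge efficiencies.
#' @return Percent change.
#' @export
percent_change_ge <- function(task_ge, rest_ge) {
  if (!is.finite(rest_ge) || rest_ge <= 0) stop("rest_ge must be > 0")
  (task_ge - rest_ge) / rest_ge * 100
}
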
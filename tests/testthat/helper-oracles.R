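# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulations so they stay independent of the
# package's implementations.

# O(N^3) all-pairs shortest paths on an edge-length matrix (0 = no edge)
floyd_warshall <- function(len) {
  n <- ncol(len)
  d <- ifelse(len > 0, len, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# random symmetric weighted graph with weights in (0, 1]
random_weighted_graph <- function(n, p_edge = 0.4) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  m <- sum(ut)
  vals <- ifelse(runif(m) < p_edge, runif(m, 0.05, 1), 0)
  w[ut] <- vals
  w + t(w)
}

# direct evaluation of weighted modularity from its defining sums
modularity_direct <- function(w, lab) {
  W <- sum(w) / 2
  S <- rowSums(w)
  total <- 0
  for (s in unique(lab)) {
    idx <- lab == s
    total <- total + sum(w[idx, idx]) / 2 / W - (sum(S[idx]) / (2 * W))^2
  }
  total
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, k) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(k + 1)) rec(c(labels, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}

# unit-weight adjacency helpers
complete_graph <- function(n) { m <- matrix(1, n, n); diag(m) <- 0; m }
path_graph <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- 1
  m
}
star_graph <- function(n, weight = 1) {
  m <- matrix(0, n, n)
  m[1, 2:n] <- m[2:n, 1] <- weight
  m
}
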
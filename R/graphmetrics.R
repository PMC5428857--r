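#' Extract the weighted adjacency matrix of a network object
#'
#' Accepts a `conn_result`, a `group_mean_network`, or a plain symmetric
#' non-negative matrix; returns the matrix.
#' @param g network object.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
adjacency <- function(g) {
  w <- if (inherits(g, "conn_result")) g$w
  else if (inherits(g, "group_mean_network")) g$mean_w
  else as.matrix(g)
  if (nrow(w) != ncol(w)) stop("adjacency must be square")
  diag(w) <- 0
  w
}

#' Network wiring cost
#'
#' Fraction of possible node pairs that carry an edge:
#' `K / (N (N - 1) / 2)`.
#'
#' @param g network object (see [adjacency()]).
#' @return scalar in `[0, 1]`.
#' @export
net_cost <- function(g) {
  w <- adjacency(g)
  n <- ncol(w)
  if (n < 2L) stop("need at least 2 nodes")
  sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}

#' Nodal strength and network strength
#'
#' Nodal strength `S_i` is the sum of the weights of all edges incident to
#' node i; network strength `S_p` is the mean of `S_i` over nodes.
#'
#' @param g network object.
#' @return list with `S_i` (named vector) and `S_p` (scalar).
#' @export
net_strength <- function(g) {
  w <- adjacency(g)
  S_i <- rowSums(w)
  list(S_i = S_i, S_p = mean(S_i))
}

#' Weighted shortest-path distance matrix
#'
#' Edge lengths are the reciprocals of the edge weights (stronger
#' correlation = shorter functional distance); unreachable pairs are `Inf`.
#'
#' @param g network object.
#' @return `N x N` distance matrix (zero diagonal).
#' @export
shortest_paths_matrix <- function(g) {
  w <- adjacency(g)
  n <- ncol(w)
  if (n < 2L) stop("need at least 2 nodes")
  len <- ifelse(w > 0, 1 / w, 0)
  gr <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(gr, algorithm = "dijkstra")
  dimnames(d) <- dimnames(w)
  d
}

#' Global efficiency
#'
#' Mean of the inverse shortest-path distances over all ordered node pairs,
#' with `1/Inf = 0` for unreachable pairs.
#'
#' @param g network object, or a precomputed distance matrix via `dist_mat`.
#' @param dist_mat optional distance matrix to reuse.
#' @return scalar efficiency.
#' @export
global_efficiency <- function(g, dist_mat = NULL) {
  d <- if (is.null(dist_mat)) shortest_paths_matrix(g) else dist_mat
  n <- ncol(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours (weights inherited); neighbourhoods with fewer than
#' two nodes contribute 0.
#'
#' @param g network object.
#' @return scalar efficiency.
#' @export
local_efficiency <- function(g) {
  w <- adjacency(g)
  n <- ncol(w)
  terms <- vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2L) return(0)
    global_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(terms)
}

#' Characteristic (weighted shortest) path length
#'
#' Arithmetic mean of the shortest-path distances over reachable ordered
#' pairs, reported together with the count of unreachable pairs
#' (Bonferroni-thresholded networks can be disconnected).
#'
#' @param g network object.
#' @param dist_mat optional distance matrix to reuse.
#' @return list with `L_p` (`NA` when no pair is reachable) and
#'   `n_unreachable_pairs`.
#' @export
characteristic_path_length <- function(g, dist_mat = NULL) {
  d <- if (is.null(dist_mat)) shortest_paths_matrix(g) else dist_mat
  off <- d[row(d) != col(d)]
  unreachable <- sum(!is.finite(off))
  reachable <- off[is.finite(off)]
  list(L_p = if (length(reachable)) mean(reachable) else NA_real_,
       n_unreachable_pairs = unreachable)
}

#' Clustering coefficient
#'
#' Binary clustering on the thresholded topology: per node, the number of
#' edges among its neighbours divided by the number of possible such edges;
#' nodes with degree < 2 contribute 0; the network value is the mean over
#' nodes. A weighted (Onnela) variant is available for sensitivity
#' analysis.
#'
#' @param g network object.
#' @param variant `"binary"` (default) or `"onnela"`.
#' @return scalar in `[0, 1]`.
#' @export
clustering_coefficient <- function(g, variant = c("binary", "onnela")) {
  w <- adjacency(g)
  variant <- match.arg(variant)
  n <- ncol(w)
  a <- (w > 0) * 1
  terms <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    d <- length(nb)
    if (d < 2L) return(0)
    if (variant == "binary") {
      k <- sum(a[nb, nb]) / 2
      k / (d * (d - 1) / 2)
    } else {
      wh <- (w / max(w))^(1 / 3)
      num <- 0
      for (j in nb) for (k in nb) if (j != k)
        num <- num + wh[i, j] * wh[j, k] * wh[k, i]
      num / (d * (d - 1))
    }
  }, numeric(1))
  mean(terms)
}

#' Cost-efficiency
#'
#' Ratio of global efficiency to wiring cost; `NA` for an empty network.
#'
#' @param g network object.
#' @return scalar, or `NA` when the cost is zero.
#' @export
cost_efficiency <- function(g) {
  co <- net_cost(g)
  if (co == 0) return(NA_real_)
  global_efficiency(g) / co
}

#' All global metrics for one network
#'
#' @param g network object.
#' @return one-row data.frame with columns `cost`, `S_p`, `E_glob`,
#'   `E_loc`, `L_p`, `C_p`, `cost_efficiency`, `Q`, `n_unreachable_pairs`.
#'   `Q` is the maximized modularity of the network's own spectral
#'   partition.
#' @export
global_metrics <- function(g) {
  w <- adjacency(g)
  d <- shortest_paths_matrix(w)
  cp <- characteristic_path_length(w, dist_mat = d)
  co <- net_cost(w)
  eg <- global_efficiency(w, dist_mat = d)
  part <- spectral_partition(w)
  data.frame(
    cost = co,
    S_p = net_strength(w)$S_p,
    E_glob = eg,
    E_loc = local_efficiency(w),
    L_p = cp$L_p,
    C_p = clustering_coefficient(w),
    cost_efficiency = if (co > 0) eg / co else NA_real_,
    Q = part$Q,
    n_unreachable_pairs = cp$n_unreachable_pairs
  )
}

#' Mean connectivity strength within a module
#'
#' Mean of the adjacency weights over the unordered node pairs of module
#' `s` (zero entries included), so values are comparable across modules of
#' different sizes.
#'
#' @param w weight matrix or network object.
#' @param partition integer module assignment per node (or a
#'   `module_partition`).
#' @param s module id.
#' @return scalar mean weight; errors for singleton modules.
#' @export
intra_module_strength <- function(w, partition, s) {
  w <- adjacency(w)
  lab <- partition_labels(partition, ncol(w))
  idx <- which(lab == s)
  if (length(idx) < 2L)
    stop("module ", s, " has fewer than 2 nodes; intra-module strength undefined")
  sub <- w[idx, idx]
  mean(sub[upper.tri(sub)])
}

#' Mean connectivity strength between two modules
#'
#' Mean of the adjacency weights over all cross pairs (i in `s`, j in `t`).
#'
#' @inheritParams intra_module_strength
#' @param t second module id, distinct from `s`.
#' @return scalar mean weight.
#' @export
inter_module_strength <- function(w, partition, s, t) {
  if (s == t) stop("s and t must be distinct modules")
  w <- adjacency(w)
  lab <- partition_labels(partition, ncol(w))
  mean(w[lab == s, lab == t])
}

partition_labels <- function(partition, n) {
  lab <- if (inherits(partition, "module_partition")) partition$assignment
  else as.integer(partition)
  if (length(lab) != n) stop("partition length does not match node count")
  lab
}
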
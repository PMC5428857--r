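#' Pearson correlation and p-value matrices for one series
#'
#' Computes the full ROI-by-ROI Pearson correlation matrix and the
#' two-sided p value of each coefficient from the t distribution with
#' `T - 2` degrees of freedom. The diagonal is set to `r = 0`, `p = 1` by
#' convention (self-connections are excluded structurally). Zero-variance
#' columns get `r = 0`, `p = 1` on all their entries, with a warning.
#'
#' @param ts an [roi_ts()] or a plain `T x N` numeric matrix.
#' @return list with symmetric matrices `r` and `p`, `n_volumes`, and
#'   `roi_labels`.
#' @export
correlation_matrix <- function(ts) {
  x <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  labels <- if (inherits(ts, "roi_ts")) ts$roi_labels else colnames(x)
  if (is.null(labels)) labels <- sprintf("ROI_%03d", seq_len(ncol(x)))
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 volumes after scrubbing")
  sds <- apply(x, 2, sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  if (length(degenerate))
    warning("zero-variance column(s): ",
            paste(labels[degenerate], collapse = ", "),
            "; their correlations set to 0 (p = 1)")
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  if (length(degenerate)) {
    p[degenerate, ] <- 1
    p[, degenerate] <- 1
  }
  diag(r) <- 0
  diag(p) <- 1
  dimnames(r) <- dimnames(p) <- list(labels, labels)
  list(r = r, p = p, n_volumes = n, roi_labels = labels)
}

new_conn_result <- function(r, p, w, mode, roi_labels) {
  structure(list(r = r, p = p, w = w, mode = mode, roi_labels = roi_labels),
            class = "conn_result")
}

#' @export
print.conn_result <- function(x, ...) {
  n <- ncol(x$w)
  k <- sum(x$w[upper.tri(x$w)] > 0)
  cat(sprintf("%s connectivity network: %d nodes, %d edges (cost %.3f)\n",
              x$mode, n, k, k / (n * (n - 1) / 2)))
  invisible(x)
}

#' Bonferroni-thresholded weighted network
#'
#' Retains edge (i, j) iff `r > 0` and `p < alpha / M`, where `M = N(N-1)/2`
#' is the number of distinct node pairs; the retained weight is the
#' correlation coefficient. Negative correlations are excluded.
#'
#' @param r,p symmetric correlation / p-value matrices (e.g. from
#'   [correlation_matrix()]).
#' @param alpha family-wise significance level before Bonferroni division.
#' @return a `conn_result` with `mode = "weighted"`.
#' @export
threshold_weighted <- function(r, p, alpha = 0.05) {
  check_conformable(r, p)
  M <- ncol(r) * (ncol(r) - 1) / 2
  w <- ifelse(r > 0 & p < alpha / M, r, 0)
  diag(w) <- 0
  new_conn_result(r, p, w, "weighted", rownames(r))
}

#' FDR-thresholded binary network
#'
#' Benjamini-Hochberg step-up over the `M = N(N-1)/2` upper-triangle
#' p values at level `q`; surviving positive-correlation edges get weight 1.
#'
#' @param r,p as in [threshold_weighted()].
#' @param q false discovery rate (default 0.01).
#' @return a `conn_result` with `mode = "binary"`.
#' @export
threshold_binary <- function(r, p, q = 0.01) {
  check_conformable(r, p)
  ut <- upper.tri(p)
  padj <- p
  padj[ut] <- p.adjust(p[ut], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  w <- ifelse(r > 0 & padj < q, 1, 0)
  diag(w) <- 0
  new_conn_result(r, p, w, "binary", rownames(r))
}

check_conformable <- function(r, p) {
  if (!all(dim(r) == dim(p)) || nrow(r) != ncol(r))
    stop("r and p must be square matrices of equal size")
  invisible(TRUE)
}

#' Group-mean network
#'
#' Edgewise arithmetic mean of the thresholded adjacency matrices of two or
#' more subjects with identical ROI labels.
#'
#' @param results list of `conn_result` objects.
#' @return object of class `group_mean_network` with `mean_w`, `n_subjects`,
#'   `roi_labels`, and (after [backbone_extract()]) a `backbone` mask.
#' @export
group_mean <- function(results) {
  if (length(results) < 2L) stop("need at least 2 subjects to average")
  labels <- results[[1]]$roi_labels
  for (r in results)
    if (!identical(r$roi_labels, labels))
      stop("ROI labels differ across subjects; cannot average")
  mean_w <- Reduce(`+`, lapply(results, `[[`, "w")) / length(results)
  structure(list(mean_w = mean_w, n_subjects = length(results),
                 roi_labels = labels, backbone = NULL),
            class = "group_mean_network")
}

#' @export
print.group_mean_network <- function(x, ...) {
  n <- ncol(x$mean_w)
  k <- sum(x$mean_w[upper.tri(x$mean_w)] > 0)
  cat(sprintf("group-mean network over %d subjects: %d nodes, %d nonzero edges%s\n",
              x$n_subjects, n, k,
              if (is.null(x$backbone)) "" else
                sprintf(", backbone %d edges",
                        sum(x$backbone[upper.tri(x$backbone)]))))
  invisible(x)
}

#' Backbone extraction by local edge significance
#'
#' Nonparametric sparsification of a weighted network: at each node, every
#' incident edge weight receives an empirical local p value equal to its
#' rank among that node's incident weights (largest weight = rank 1 =
#' smallest p) divided by the node's degree. Tied weights all take the
#' maximum rank of the tie group (the conservative choice: ties never gain
#' significance). An edge enters the backbone iff it is locally significant
#' (p <= alpha) at one or more of its endpoints, so the mask is symmetric.
#'
#' @param g a `group_mean_network` or a plain symmetric weight matrix.
#' @param alpha local significance level (default 0.05).
#' @return for a `group_mean_network`, the same object with its `backbone`
#'   slot filled; for a matrix, the 0/1 backbone mask.
#' @export
backbone_extract <- function(g, alpha = 0.05) {
  w <- if (inherits(g, "group_mean_network")) g$mean_w else as.matrix(g)
  n <- ncol(w)
  if (!any(w[upper.tri(w)] > 0)) stop("network has no positive edge")
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    d <- length(nb)
    if (d == 0L) next
    wt <- w[i, nb]
    # max-rank ties: rank = number of incident weights >= this weight
    rk <- vapply(wt, function(v) sum(wt >= v), integer(1))
    sig <- nb[rk / d <= alpha]
    keep[i, sig] <- TRUE
    keep[sig, i] <- TRUE
  }
  mask <- (keep | t(keep)) * 1L
  diag(mask) <- 0L
  if (!any(mask == 1L)) stop("backbone empty; relax alpha")
  if (inherits(g, "group_mean_network")) {
    g$backbone <- mask
    g
  } else mask
}

#' Read/write square matrices with an ROI-label header row
#'
#' The on-disk dialect is whitespace-delimited text: one header row of ROI
#' labels, then one row of numbers per node, at 12 significant digits.
#'
#' @param mat square numeric matrix with ROI dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(mat, path) {
  write_num_tsv(mat, path, col_names = colnames(mat))
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  m <- as.matrix(read.delim(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  m
}

#' Export a network for surface rendering
#'
#' Writes BrainNet-viewer-style plain-text `.node` (label, module id,
#' strength) and `.edge` (square weight matrix) companion files. Node
#' coordinates are not known to this package and are written as zeros,
#' to be substituted from an atlas table.
#'
#' @param w symmetric weight matrix with ROI labels.
#' @param prefix output path prefix (writes `<prefix>.node`,
#'   `<prefix>.edge`).
#' @param modules optional integer module id per node (colour column).
#' @return invisibly, the two paths.
#' @export
export_brainnet <- function(w, prefix, modules = NULL) {
  n <- ncol(w)
  if (is.null(modules)) modules <- rep(1L, n)
  strength <- rowSums(w)
  node <- data.frame(x = 0, y = 0, z = 0, colour = modules,
                     size = formatC(strength, digits = 6, format = "g"),
                     label = colnames(w))
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  write.table(node, node_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(formatC(w, digits = 12, format = "g"), edge_path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(node_path, edge_path))
}
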
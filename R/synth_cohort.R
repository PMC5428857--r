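#' Specify a synthetic longitudinal cohort
#'
#' Describes a two-group (MT/RT) by two-session (Pre/Post) cohort of regional
#' time series whose population correlation matrix is block-structured:
#' `r_intra` within each planted module, `r_inter` between modules, with
#' optional cell-specific additive changes (`delta_intra`, `delta_inter`)
#' that emulate group-by-time connectivity effects. Every cell's implied
#' correlation matrix is checked for positive semidefiniteness at
#' construction; invalid parameter combinations are rejected rather than
#' projected, so the generating truth is always exact.
#'
#' @param n_per_group subjects per group.
#' @param n_nodes number of regions (network nodes), `N`.
#' @param module_sizes integer vector of planted module sizes; must sum to
#'   `n_nodes`. Default: five roughly equal modules, mirroring the canonical
#'   five resting-state systems (DMN, SAN, SMN, FPN, VN).
#' @param n_volumes time points per scan, `T` (default 175, i.e. a 6-minute
#'   acquisition at TR = 2 s with 5 dummy volumes discarded).
#' @param tr_seconds repetition time in seconds.
#' @param r_intra baseline within-module correlation, in `[0, 1)`.
#' @param r_inter baseline between-module correlation; `|r_inter| < r_intra`.
#' @param delta_intra data.frame with columns `group`, `session`, `module`,
#'   `delta`: additive change to `r_intra` inside one module for one
#'   group-session cell. Empty by default.
#' @param delta_inter data.frame with columns `group`, `session`, `module1`,
#'   `module2`, `delta`: additive change to `r_inter` for one module pair.
#' @param noise_sd marginal standard deviation of every regional signal.
#' @param ar1 optional lag-1 autoregressive coefficient for stress-testing;
#'   the default 0 gives independent volumes, matching the assumption that
#'   only the zero-lag correlation structure matters downstream.
#' @param seed integer seed; equal seeds give bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20,
                        n_nodes = 64,
                        module_sizes = NULL,
                        n_volumes = 175,
                        tr_seconds = 2,
                        r_intra = 0.6,
                        r_inter = 0.05,
                        delta_intra = NULL,
                        delta_inter = NULL,
                        noise_sd = 1,
                        ar1 = 0,
                        seed = 1L) {
  if (is.null(module_sizes)) {
    base <- n_nodes %/% 5L
    module_sizes <- rep(base, 5L)
    module_sizes[seq_len(n_nodes - 5L * base)] <-
      module_sizes[seq_len(n_nodes - 5L * base)] + 1L
  }
  module_sizes <- as.integer(module_sizes)
  if (sum(module_sizes) != n_nodes)
    stop("module_sizes must sum to n_nodes (", sum(module_sizes),
         " != ", n_nodes, ")")
  if (any(module_sizes < 1L)) stop("module sizes must be >= 1")
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (n_volumes < 2L) stop("n_volumes must be >= 2")
  if (tr_seconds <= 0) stop("tr_seconds must be positive")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (r_intra < 0 || r_intra >= 1) stop("r_intra must lie in [0, 1)")
  if (abs(r_inter) >= max(r_intra, .Machine$double.eps) && r_inter != 0)
    stop("|r_inter| must be smaller than r_intra")
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)")
  empty_intra <- data.frame(group = character(), session = character(),
                            module = integer(), delta = numeric())
  empty_inter <- data.frame(group = character(), session = character(),
                            module1 = integer(), module2 = integer(),
                            delta = numeric())
  delta_intra <- if (is.null(delta_intra)) empty_intra else
    as.data.frame(delta_intra)
  delta_inter <- if (is.null(delta_inter)) empty_inter else
    as.data.frame(delta_inter)
  spec <- structure(list(
    n_per_group = as.integer(n_per_group),
    n_nodes = as.integer(n_nodes),
    module_sizes = module_sizes,
    n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds,
    r_intra = r_intra,
    r_inter = r_inter,
    delta_intra = delta_intra,
    delta_inter = delta_inter,
    noise_sd = noise_sd,
    ar1 = ar1,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  # reject non-PSD parameter sets up front so generation cannot silently
  # change the planted truth
  for (g in c("MT", "RT")) for (s in c("Pre", "Post"))
    cell_correlation(spec, g, s)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  ", x$n_per_group, "subjects/group x 2 groups x 2 sessions;",
      x$n_volumes, "volumes x", x$n_nodes, "ROIs (TR =", x$tr_seconds, "s)\n")
  cat("  modules:", paste(x$module_sizes, collapse = "+"),
      "| r_intra =", x$r_intra, "r_inter =", x$r_inter, "\n")
  cat("  planted effects:", nrow(x$delta_intra), "intra,",
      nrow(x$delta_inter), "inter; seed =", x$seed, "\n")
  invisible(x)
}

#' Planted module labels of a cohort specification
#'
#' @param spec a [cohort_spec()].
#' @return integer vector of length `n_nodes` giving each node's module id.
#' @export
planted_partition <- function(spec) {
  rep(seq_along(spec$module_sizes), spec$module_sizes)
}

#' Block-structured correlation matrix
#'
#' Builds the `N x N` correlation matrix with unit diagonal whose entry
#' `(i, j)` is the within-module correlation of the shared module when `i`
#' and `j` are co-modular and the between-module correlation otherwise.
#' `r_intra` and `r_inter` may be scalars or, respectively, one value per
#' module and a symmetric module-by-module matrix (diagonal ignored).
#'
#' @param module_sizes integer vector of module sizes.
#' @param r_intra within-module correlation(s).
#' @param r_inter between-module correlation(s).
#' @param check if `TRUE` (default), reject matrices that are not positive
#'   semidefinite, reporting the offending minimum eigenvalue.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
build_block_correlation <- function(module_sizes, r_intra, r_inter,
                                    check = TRUE) {
  module_sizes <- as.integer(module_sizes)
  m <- length(module_sizes)
  n <- sum(module_sizes)
  lab <- rep(seq_len(m), module_sizes)
  if (length(r_intra) == 1L) r_intra <- rep(r_intra, m)
  if (length(r_intra) != m) stop("r_intra must be scalar or one per module")
  if (is.matrix(r_inter)) {
    if (!all(dim(r_inter) == m)) stop("r_inter matrix must be m x m")
    if (max(abs(r_inter - t(r_inter))) > 1e-12)
      stop("r_inter matrix must be symmetric")
    rint <- r_inter
  } else {
    if (length(r_inter) != 1L) stop("r_inter must be scalar or m x m matrix")
    rint <- matrix(r_inter, m, m)
  }
  R <- rint[lab, lab, drop = FALSE]
  for (s in seq_len(m)) {
    idx <- which(lab == s)
    R[idx, idx] <- r_intra[s]
  }
  diag(R) <- 1
  dimnames(R) <- NULL
  if (check) {
    ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop(sprintf(
        "parameters do not define a positive semidefinite correlation matrix (min eigenvalue %.6g)",
        ev))
  }
  R
}

# correlation matrix of one (group, session) cell, with deltas applied
cell_correlation <- function(spec, group, session) {
  m <- length(spec$module_sizes)
  r_intra <- rep(spec$r_intra, m)
  r_inter <- matrix(spec$r_inter, m, m)
  di <- spec$delta_intra
  if (nrow(di)) {
    sel <- di$group == group & di$session == session
    for (k in which(sel)) {
      mod <- as.integer(di$module[k])
      if (mod < 1L || mod > m) stop("delta_intra references unknown module ", mod)
      r_intra[mod] <- r_intra[mod] + di$delta[k]
    }
  }
  de <- spec$delta_inter
  if (nrow(de)) {
    sel <- de$group == group & de$session == session
    for (k in which(sel)) {
      a <- as.integer(de$module1[k]); b <- as.integer(de$module2[k])
      if (a == b) stop("delta_inter must reference two distinct modules")
      r_inter[a, b] <- r_inter[a, b] + de$delta[k]
      r_inter[b, a] <- r_inter[a, b]
    }
  }
  build_block_correlation(spec$module_sizes, r_intra, r_inter, check = TRUE)
}

#' One subject-session matrix of regional time series
#'
#' @param subject_id subject token.
#' @param group `"MT"` or `"RT"`.
#' @param session `"Pre"` or `"Post"`.
#' @param data numeric `T x N` matrix: rows are volumes, columns are ROIs.
#' @param tr_seconds repetition time in seconds.
#' @param roi_labels unique labels, one per column; defaults to
#'   `ROI_001 ...`.
#' @param motion optional `T x 6` rigid-body motion matrix (tx, ty, tz in
#'   mm; rx, ry, rz in radians).
#' @return An object of class `roi_ts`.
#' @export
roi_ts <- function(subject_id, group, session, data, tr_seconds = 2,
                   roi_labels = NULL, motion = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("time series needs at least 2 volumes and 2 ROIs")
  if (anyNA(data)) stop("time series contains missing values")
  group <- match.arg(group, c("MT", "RT"))
  session <- match.arg(session, c("Pre", "Post"))
  if (is.null(roi_labels)) roi_labels <- colnames(data)
  if (is.null(roi_labels))
    roi_labels <- sprintf("ROI_%03d", seq_len(ncol(data)))
  if (length(roi_labels) != ncol(data) || anyDuplicated(roi_labels))
    stop("roi_labels must be unique and match the column count")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != nrow(data) || ncol(motion) != 6L)
      stop("motion must be a T x 6 matrix matching the time series")
  }
  colnames(data) <- roi_labels
  structure(list(subject_id = as.character(subject_id), group = group,
                 session = session, tr_seconds = tr_seconds, data = data,
                 roi_labels = roi_labels, motion = motion),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: subject %s [%s/%s], %d volumes x %d ROIs, TR = %g s%s\n",
              x$subject_id, x$group, x$session, nrow(x$data), ncol(x$data),
              x$tr_seconds,
              if (is.null(x$motion)) "" else ", with motion table"))
  invisible(x)
}

#' Generate a synthetic longitudinal cohort
#'
#' Draws, for every subject and session, `T` independent (or AR(1), if
#' `spec$ar1 != 0`) multivariate-normal volumes under the cell's block
#' correlation matrix scaled by `noise_sd`. Subject identity is preserved
#' across sessions; identical seeds reproduce the cohort bit for bit.
#'
#' @param spec a [cohort_spec()].
#' @param motion_spikes optional data.frame with columns `subject_id`,
#'   `session`, `volume`, `amplitude_mm`: inserts a single-volume x-translation
#'   displacement in an otherwise all-zero motion table, to exercise
#'   scrubbing. When `NULL` no motion tables are attached.
#' @return list of `roi_ts` objects (2 groups x 2 sessions x `n_per_group`).
#' @export
generate_cohort <- function(spec, motion_spikes = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  R <- list()
  for (g in c("MT", "RT")) for (s in c("Pre", "Post"))
    R[[paste(g, s)]] <- chol(cell_correlation(spec, g, s) +
                               diag(1e-10, spec$n_nodes))
  roi_labels <- sprintf("ROI_%03d", seq_len(spec$n_nodes))
  out <- list()
  for (g in c("MT", "RT")) {
    for (i in seq_len(spec$n_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      for (s in c("Pre", "Post")) {
        U <- R[[paste(g, s)]]
        Z <- matrix(rnorm(spec$n_volumes * spec$n_nodes),
                    spec$n_volumes, spec$n_nodes)
        X <- Z %*% U
        if (spec$ar1 != 0) {
          phi <- spec$ar1
          X[1, ] <- X[1, ]  # stationary start: innovations scaled below
          for (t in 2:nrow(X))
            X[t, ] <- phi * X[t - 1, ] + sqrt(1 - phi^2) * X[t, ]
        }
        X <- X * spec$noise_sd
        motion <- NULL
        if (!is.null(motion_spikes)) {
          motion <- matrix(0, spec$n_volumes, 6)
          sel <- motion_spikes$subject_id == sid &
            motion_spikes$session == s
          for (k in which(sel))
            motion[motion_spikes$volume[k], 1] <- motion_spikes$amplitude_mm[k]
        }
        out[[paste(sid, s, sep = "_")]] <-
          roi_ts(sid, g, s, X, tr_seconds = spec$tr_seconds,
                 roi_labels = roi_labels, motion = motion)
      }
    }
  }
  out
}

#' Write a cohort to tab-separated files
#'
#' One TSV per subject-session (header row = ROI labels, one row per
#' volume), one motion TSV where a motion table is present, plus a manifest
#' TSV with columns `subject_id`, `group`, `session`, `timeseries_path`,
#' `motion_path`. Numeric values are written at 15 significant digits so the
#' cohort round-trips through [read_cohort()] to within 1e-12.
#'
#' @param cohort list of `roi_ts` objects.
#' @param dir output directory (created if needed).
#' @param overwrite overwrite an existing manifest? Default `FALSE`.
#' @return path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  if (length(cohort) == 0L) stop("cohort is empty; nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.tsv")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists at ", manifest_path,
         "; pass overwrite = TRUE to replace it")
  rows <- lapply(cohort, function(ts) {
    base <- sprintf("%s_%s", ts$subject_id, ts$session)
    ts_file <- paste0(base, ".tsv")
    write_num_tsv(ts$data, file.path(dir, ts_file), col_names = ts$roi_labels)
    motion_file <- ""
    if (!is.null(ts$motion)) {
      motion_file <- paste0(base, "_motion.tsv")
      write_num_tsv(ts$motion, file.path(dir, motion_file),
                    col_names = c("tx", "ty", "tz", "rx", "ry", "rz"))
    }
    data.frame(subject_id = ts$subject_id, group = ts$group,
               session = ts$session, timeseries_path = ts_file,
               motion_path = motion_file, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path path to the manifest TSV.
#' @param tr_seconds repetition time to attach to each series.
#' @return list of `roi_ts` objects, in manifest order.
#' @export
read_cohort <- function(manifest_path, tr_seconds = 2) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  manifest <- read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "session", "timeseries_path")
  if (!all(need %in% names(manifest)))
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "))
  dir <- dirname(manifest_path)
  out <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    dat <- as.matrix(read.delim(file.path(dir, manifest$timeseries_path[k]),
                                check.names = FALSE))
    motion <- NULL
    mp <- manifest$motion_path
    if (!is.null(mp) && !is.na(mp[k]) && nzchar(mp[k]))
      motion <- as.matrix(read.delim(file.path(dir, mp[k])))
    out[[k]] <- roi_ts(manifest$subject_id[k], manifest$group[k],
                       manifest$session[k], dat, tr_seconds = tr_seconds,
                       roi_labels = colnames(dat), motion = motion)
    names(out)[k] <- paste(manifest$subject_id[k], manifest$session[k],
                           sep = "_")
  }
  out
}

# numeric TSV at 15 significant digits (round-trips doubles to <= 1e-12)
write_num_tsv <- function(mat, path, col_names = colnames(mat)) {
  txt <- matrix(formatC(mat, digits = 15, format = "g"),
                nrow(mat), ncol(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(col_names, collapse = "\t"), con)
  writeLines(apply(txt, 1, paste, collapse = "\t"), con)
  invisible(path)
}
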
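test_that("correlation matrix matches the naive covariance-formula oracle", {
  set.seed(11)
  x <- matrix(rnorm(200), 50, 4)
  cp <- correlation_matrix(x)
  # oracle: direct sum((x - xbar)(y - ybar)) formulation per pair
  for (i in 1:3) for (j in (i + 1):4) {
    xi <- x[, i] - mean(x[, i]); yj <- x[, j] - mean(x[, j])
    r_oracle <- sum(xi * yj) / sqrt(sum(xi^2) * sum(yj^2))
    expect_equal(cp$r[i, j], r_oracle, tolerance = 1e-12)
    t_or <- r_oracle * sqrt(48 / (1 - r_oracle^2))
    expect_equal(cp$p[i, j], 2 * pt(-abs(t_or), 48), tolerance = 1e-12)
  }
  expect_equal(diag(cp$r), rep(0, 4), ignore_attr = TRUE)
  expect_equal(diag(cp$p), rep(1, 4), ignore_attr = TRUE)
})

test_that("perfectly (anti)correlated and degenerate columns are handled", {
  set.seed(2)
  base <- rnorm(30)
  x <- cbind(base, base, -base, rnorm(30), rep(1, 30))
  expect_warning(cp <- correlation_matrix(x), "zero-variance")
  expect_equal(cp$r[1, 2], 1)
  expect_lt(cp$p[1, 2], 1e-12)
  expect_equal(cp$r[1, 3], -1)
  expect_equal(cp$r[5, 1], 0)
  expect_equal(cp$p[5, 1], 1)
})

test_that("Bonferroni weighted thresholding keeps only positive survivors", {
  r <- matrix(c(0, 0.8, -0.9, 0.8, 0, 0.5, -0.9, 0.5, 0), 3, 3)
  p0 <- matrix(1e-12, 3, 3); diag(p0) <- 1
  # all p essentially zero: negative edge still excluded
  res <- threshold_weighted(r, p0)
  expect_equal(res$w[1, 2], 0.8)
  expect_equal(res$w[1, 3], 0)          # negative correlation excluded
  expect_equal(res$w[2, 3], 0.5)
  expect_true(isSymmetric(res$w))
  expect_equal(diag(res$w), rep(0, 3))
  # p all 1: empty network
  p1 <- matrix(1, 3, 3)
  expect_equal(net_cost(threshold_weighted(r, p1)), 0)
  # weights never invented: support of w is a subset of positive r
  expect_true(all(res$w[res$w > 0] == r[res$w > 0]))
})

test_that("stricter alpha yields a subset edge set (monotonicity)", {
  set.seed(4)
  x <- matrix(rnorm(40 * 10), 40, 10)
  cp <- correlation_matrix(x)
  lax <- threshold_weighted(cp$r, cp$p, alpha = 0.5)
  strict <- threshold_weighted(cp$r, cp$p, alpha = 0.05)
  expect_true(all(which(strict$w > 0) %in% which(lax$w > 0)))
})

test_that("binary FDR thresholding agrees with the BH step-up oracle", {
  # toy: 4 tests with p = {.001, .004, .03, .9} at q = .01
  pvec <- c(0.001, 0.004, 0.03, 0.9)
  q <- 0.01
  r <- matrix(0.5, 4, 4); diag(r) <- 0
  p <- matrix(1, 4, 4)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3))
  for (e in seq_len(4)) {
    p[pairs[e, 1], pairs[e, 2]] <- pvec[e]
    p[pairs[e, 2], pairs[e, 1]] <- pvec[e]
  }
  res <- threshold_binary(r, p, q = q)
  got <- vapply(seq_len(4), function(e) res$w[pairs[e, 1], pairs[e, 2]],
                numeric(1))
  # explicit step-up oracle over the matrix's M = 6 upper-triangle p values:
  # find the largest k with p_(k) <= k q / M; keep p <= p_(k)
  all_p <- c(pvec, 1, 1)
  sorted <- sort(all_p)
  k <- max(c(0, which(sorted <= seq_along(sorted) * q / length(sorted))))
  cut <- if (k > 0) sorted[k] else -1
  expect_equal(got, as.numeric(pvec <= cut))
  expect_equal(sum(res$w) / 2, sum(all_p <= cut))
  # boundary: all p equal and below q keeps every positive edge
  p_all <- matrix(0.005, 4, 4); diag(p_all) <- 1
  res2 <- threshold_binary(r, p_all, q = 0.01)
  expect_equal(sum(res2$w[upper.tri(res2$w)]), 6)
  expect_true(all(res2$w %in% c(0, 1)))
  # p all 1: empty
  expect_equal(net_cost(threshold_binary(r, matrix(1, 4, 4))), 0)
})

test_that("group mean is the elementwise average and checks labels", {
  set.seed(6)
  mk <- function(seed) {
    set.seed(seed)
    cp <- correlation_matrix(matrix(rnorm(30 * 6), 30, 6))
    threshold_weighted(cp$r, cp$p, alpha = 0.9)
  }
  nets <- lapply(1:10, mk)
  gm <- group_mean(nets)
  oracle <- Reduce(`+`, lapply(nets, `[[`, "w")) / 10
  expect_lt(max(abs(gm$mean_w - oracle)), 1e-12)
  expect_equal(gm$n_subjects, 10)
  # identical inputs: mean equals input
  gm2 <- group_mean(list(nets[[1]], nets[[1]]))
  expect_equal(gm2$mean_w, nets[[1]]$w)
  # two inputs with 0 and 0.8 on one edge average to 0.4
  a <- nets[[1]]; b <- nets[[1]]
  a$w[1, 2] <- a$w[2, 1] <- 0; b$w[1, 2] <- b$w[2, 1] <- 0.8
  expect_equal(group_mean(list(a, b))$mean_w[1, 2], 0.4)
  # label mismatch errors
  bad <- nets[[1]]; bad$roi_labels <- rev(bad$roi_labels)
  expect_error(group_mean(list(nets[[1]], bad)), "labels")
})

test_that("backbone keeps locally significant edges only", {
  # star with 40 leaves: one dominant edge at local p = 1/40
  w <- star_graph(41, weight = 0.1)
  w[1, 2] <- w[2, 1] <- 0.9
  mask <- backbone_extract(w, alpha = 0.05)
  expect_equal(mask[1, 2], 1L)
  expect_equal(sum(mask), 2)            # only that edge, symmetric
  # alpha = 1 keeps every edge
  mask_all <- backbone_extract(w, alpha = 1)
  expect_equal(mask_all, (w > 0) * 1L)
  # all-equal weights at modest degree: ties take the max rank, none pass
  expect_error(backbone_extract(complete_graph(10) * 0.5, alpha = 0.05),
               "backbone empty; relax alpha")
  expect_error(backbone_extract(matrix(0, 4, 4)), "no positive edge")
})

test_that("backbone density is monotone in alpha and matches enumeration", {
  set.seed(8)
  w <- random_weighted_graph(20, 0.6)
  sparse <- backbone_extract(w, alpha = 0.2)
  dense <- backbone_extract(w, alpha = 0.6)
  expect_true(all(sparse <= dense))
  # brute-force oracle: recompute each edge's two local p values directly
  oracle <- matrix(0L, 20, 20)
  for (i in 1:19) for (j in (i + 1):20) {
    if (w[i, j] == 0) next
    pv <- function(node, other) {
      inc <- w[node, ][w[node, ] > 0]
      sum(inc >= w[node, other]) / length(inc)
    }
    if (min(pv(i, j), pv(j, i)) <= 0.2)
      oracle[i, j] <- oracle[j, i] <- 1L
  }
  expect_equal(sparse, oracle)
})

test_that("matrices round-trip through the text dialect", {
  set.seed(12)
  cp <- correlation_matrix(matrix(rnorm(120), 30, 4))
  res <- threshold_weighted(cp$r, cp$p, alpha = 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(res$w, path)
  back <- read_matrix_tsv(path)
  expect_lt(max(abs(back - res$w)), 1e-12)
  expect_equal(colnames(back), colnames(res$w))
  # BrainNet-style export writes the companion pair
  prefix <- withr::local_tempfile()
  export_brainnet(res$w, prefix, modules = c(1, 1, 2, 2))
  expect_true(file.exists(paste0(prefix, ".node")))
  expect_true(file.exists(paste0(prefix, ".edge")))
})
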
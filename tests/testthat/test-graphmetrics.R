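test_that("complete unit-weight graphs satisfy the identity suite", {
  for (n in 3:8) {
    w <- complete_graph(n)
    expect_identical(net_cost(w), 1)
    expect_identical(global_efficiency(w), 1)
    expect_identical(local_efficiency(w), 1)
    expect_identical(clustering_coefficient(w), 1)
    expect_identical(characteristic_path_length(w)$L_p, 1)
    expect_identical(net_strength(w)$S_p, n - 1)
  }
})

test_that("cost counts edges over possible pairs", {
  expect_equal(net_cost(path_graph(4)), 0.5)
  expect_equal(net_cost(matrix(0, 4, 4)), 0)
})

test_that("strength is the row sum and its mean", {
  s <- net_strength(star_graph(4, weight = 0.5))
  expect_equal(as.numeric(s$S_i), c(1.5, 0.5, 0.5, 0.5))
  expect_equal(s$S_p, 0.75)
  set.seed(21)
  w <- random_weighted_graph(12)
  s <- net_strength(w)
  expect_lt(max(abs(s$S_i - rowSums(w))), 1e-12)
  expect_equal(mean(s$S_i), s$S_p, tolerance = 1e-12)
})

test_that("shortest paths use reciprocal-weight lengths", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(shortest_paths_matrix(w)[1, 2], 2)
  chain <- matrix(0, 3, 3)
  chain[1, 2] <- chain[2, 1] <- chain[2, 3] <- chain[3, 2] <- 1
  expect_equal(shortest_paths_matrix(chain)[1, 3], 2)
})

test_that("path-based metrics match the Floyd-Warshall oracle", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    w <- random_weighted_graph(n, p_edge = runif(1, 0.2, 0.8))
    if (!any(w > 0)) next
    d <- shortest_paths_matrix(w)
    d_oracle <- floyd_warshall(ifelse(w > 0, 1 / w, 0))
    expect_equal(d, d_oracle, tolerance = 1e-12, ignore_attr = TRUE)
    inv <- 1 / d_oracle; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
    expect_equal(global_efficiency(w), sum(inv) / (n * (n - 1)),
                 tolerance = 1e-12)
    off <- d_oracle[row(d_oracle) != col(d_oracle)]
    cp <- characteristic_path_length(w)
    expect_equal(cp$n_unreachable_pairs, sum(!is.finite(off)))
    if (any(is.finite(off)))
      expect_equal(cp$L_p, mean(off[is.finite(off)]), tolerance = 1e-12)
  }
})

test_that("disconnected graphs report unreachable pairs, not failures", {
  expect_equal(global_efficiency(diag(0, 2)), 0)
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1
  cp <- characteristic_path_length(dyads)
  expect_equal(cp$L_p, 1)
  expect_equal(cp$n_unreachable_pairs, 8)
  none <- characteristic_path_length(matrix(0, 3, 3))
  expect_true(is.na(none$L_p))
  expect_equal(none$n_unreachable_pairs, 6)
})

test_that("path graph path length matches pair enumeration", {
  # N=3 chain: ordered distances 1,1,2 twice -> mean 4/3
  expect_equal(characteristic_path_length(path_graph(3))$L_p, 4 / 3)
})

test_that("local efficiency and clustering on the triangle-plus-pendant", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 3] <- w[1, 3] <- w[3, 4] <- 1
  w <- pmax(w, t(w))
  # clustering by hand: nodes 1,2 closed (1), node 3 has K=1 of D=3 pairs
  expect_equal(clustering_coefficient(w), (1 + 1 + 1 / 3 + 0) / 4)
  # local efficiency by exhaustive per-node subgraph oracle
  terms <- vapply(1:4, function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    sub <- w[nb, nb, drop = FALSE]
    d <- floyd_warshall(ifelse(sub > 0, 1 / sub, 0))
    inv <- 1 / d; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
    sum(inv) / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  expect_equal(local_efficiency(w), mean(terms), tolerance = 1e-12)
  expect_equal(local_efficiency(star_graph(5)), 0)
  expect_equal(clustering_coefficient(star_graph(5)), 0)
})

test_that("cost-efficiency composes efficiency over cost", {
  expect_equal(cost_efficiency(complete_graph(5)), 1)
  w <- path_graph(4)
  expect_equal(cost_efficiency(w), global_efficiency(w) / 0.5,
               tolerance = 1e-12)
  expect_true(is.na(cost_efficiency(matrix(0, 3, 3))))
})

test_that("removing an edge never increases cost, strength or efficiency", {
  set.seed(55)
  for (rep in 1:5) {
    w <- random_weighted_graph(10, 0.5)
    edges <- which(upper.tri(w) & w > 0)
    if (!length(edges)) next
    drop <- sample(edges, 1)
    w2 <- w
    w2[drop] <- 0
    w2[cbind(col(w)[drop], row(w)[drop])] <- 0
    expect_lte(net_cost(w2), net_cost(w))
    expect_lte(net_strength(w2)$S_p, net_strength(w)$S_p)
    expect_lte(global_efficiency(w2), global_efficiency(w) + 1e-12)
  }
})

test_that("module strength summaries are pairwise means", {
  w <- matrix(0.4, 6, 6); diag(w) <- 0
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(intra_module_strength(w, lab, 1), 0.4)
  w2 <- w; w2[1:3, 1:3] <- 0
  expect_equal(intra_module_strength(w2, lab, 1), 0)
  w3 <- matrix(0, 6, 6); w3[1:3, 4:6] <- 0.2; w3 <- pmax(w3, t(w3))
  expect_equal(inter_module_strength(w3, lab, 1, 2), 0.2)
  expect_equal(inter_module_strength(w2, lab, 1, 2), 0.4)
  set.seed(77)
  w4 <- random_weighted_graph(9)
  lab4 <- c(1, 1, 1, 1, 2, 2, 2, 2, 2)
  sub <- w4[lab4 == 1, lab4 == 1]
  expect_equal(intra_module_strength(w4, lab4, 1),
               mean(sub[upper.tri(sub)]), tolerance = 1e-12)
  expect_equal(inter_module_strength(w4, lab4, 1, 2),
               mean(w4[lab4 == 1, lab4 == 2]), tolerance = 1e-12)
  expect_error(intra_module_strength(w4, c(1, rep(2, 8)), 1), "singleton|fewer")
  expect_error(inter_module_strength(w4, lab4, 2, 2), "distinct")
})
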
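make_frame <- function(n_per_group = 10, seed = 1, mt_post_shift = 0,
                       group_offset = 0, covariates = FALSE) {
  set.seed(seed)
  ids <- c(sprintf("MT_%02d", seq_len(n_per_group)),
           sprintf("RT_%02d", seq_len(n_per_group)))
  grp <- rep(c("MT", "RT"), each = n_per_group)
  pre <- rnorm(2 * n_per_group)
  post <- rnorm(2 * n_per_group)
  post[grp == "MT"] <- post[grp == "MT"] + mt_post_shift
  pre <- pre + group_offset * (grp == "MT")
  post <- post + group_offset * (grp == "MT")
  covs <- NULL
  if (covariates)
    covs <- data.frame(age = rep(round(rnorm(2 * n_per_group, 65, 3)), 2),
                       gender = rep(sample(c("F", "M"), 2 * n_per_group,
                                           replace = TRUE), 2),
                       education = rep(round(rnorm(2 * n_per_group, 12, 3)), 2))
  long_metric_frame(rep(ids, 2), rep(grp, 2),
                    rep(c("Pre", "Post"), each = 2 * n_per_group),
                    c(pre, post), covariates = covs)
}

test_that("summary t test matches the pooled-variance formula", {
  eq <- ttest_from_summary(5, 1, 10, 5, 2, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
  set.seed(14)
  for (rep in 1:5) {
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, .5, 2); s2 <- runif(1, .5, 2)
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    got <- ttest_from_summary(m1, s1, n1, m2, s2, n2)
    sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
    t_or <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    expect_equal(got$t, t_or, tolerance = 1e-12)
    expect_equal(got$df, n1 + n2 - 2)
    expect_equal(got$p, 2 * pt(-abs(t_or), n1 + n2 - 2), tolerance = 1e-12)
  }
})

test_that("baseline age comparison lands where the demographics table reports", {
  got <- ttest_from_summary(64.78, 2.71, 23, 64.68, 2.19, 22)
  expect_gte(abs(got$t), 0.12)
  expect_lte(abs(got$t), 0.15)
  expect_gt(got$p, 0.5)
})

test_that("2x2 chi-square matches the hand formula and is swap-symmetric", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$X2, 0)
  set.seed(15)
  for (rep in 1:5) {
    cnt <- sample(3:30, 4, replace = TRUE)
    got <- chi_square_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    tab <- matrix(cnt, 2, 2, byrow = TRUE)
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$X2, sum((tab - expd)^2 / expd), tolerance = 1e-12)
    # symmetric under row and column swaps
    expect_equal(chi_square_2x2(cnt[3], cnt[4], cnt[1], cnt[2])$X2, got$X2)
    expect_equal(chi_square_2x2(cnt[2], cnt[1], cnt[4], cnt[3])$X2, got$X2)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "marginal")
})

test_that("mixed ANOVA matches the classical aov decomposition on balanced data", {
  for (seed in c(3, 4)) {
    fr <- make_frame(n_per_group = 8, seed = seed)
    got <- mixed_anova(fr)
    dat <- as.data.frame(fr)
    dat$subject_id <- factor(dat$subject_id)
    dat$group <- factor(dat$group)
    dat$session <- factor(dat$session, levels = c("Pre", "Post"))
    oracle <- summary(aov(value ~ group * session + Error(subject_id),
                          data = dat))
    bet <- oracle[["Error: subject_id"]][[1]]
    wit <- oracle[["Error: Within"]][[1]]
    rownames(bet) <- trimws(rownames(bet))
    rownames(wit) <- trimws(rownames(wit))
    expect_equal(got$group$F, bet["group", "F value"], tolerance = 1e-8)
    expect_equal(got$time$F, wit["session", "F value"], tolerance = 1e-8)
    expect_equal(got$interaction$F,
                 wit["group:session", "F value"], tolerance = 1e-8)
    expect_equal(got$group$p, bet["group", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(got$interaction$p,
                 wit["group:session", "Pr(>F)"], tolerance = 1e-8)
    expect_equal(got$interaction$df2, 2 * 8 - 2)
  }
})

test_that("mixed ANOVA effect structure responds to construction", {
  # pure additive group offset, no time effect: big group F, near-zero interaction
  fr <- make_frame(n_per_group = 12, seed = 6, group_offset = 50)
  got <- mixed_anova(fr)
  expect_gt(got$group$F, 100)
  expect_lt(got$interaction$F, 10)
  # invariance to a global constant shift
  fr2 <- fr; fr2$value <- fr2$value + 123.4
  got2 <- mixed_anova(fr2)
  expect_equal(got$group$F, got2$group$F, tolerance = 1e-8)
  expect_equal(got$interaction$F, got2$interaction$F, tolerance = 1e-8)
  # interaction invariant to group-wise constant offsets
  fr3 <- fr; fr3$value <- fr3$value + 77 * (fr3$group == "RT")
  expect_equal(mixed_anova(fr3)$interaction$F, got$interaction$F,
               tolerance = 1e-8)
})

test_that("covariate adjustment runs and leaves df accounting consistent", {
  fr <- make_frame(n_per_group = 10, seed = 8, covariates = TRUE)
  got <- mixed_anova(fr, covariates = "on")
  # 20 subjects - intercept - group - 3 covariates = 15 error df
  expect_equal(got$interaction$df2, 15)
  expect_true(all(c(got$group$p, got$time$p, got$interaction$p) >= 0))
  off <- mixed_anova(fr, covariates = "off")
  expect_equal(off$interaction$df2, 18)
})

test_that("degenerate and unpaired inputs are flagged, not mis-tested", {
  fr <- make_frame(n_per_group = 5, seed = 9)
  fr$value <- 1
  got <- mixed_anova(fr)
  expect_true(got$degenerate)
  expect_true(is.na(got$interaction$p))
  fr2 <- make_frame(n_per_group = 5, seed = 10)
  fr2 <- fr2[-1, ]  # drop one Pre row -> subject unpaired
  expect_warning(got2 <- mixed_anova(fr2), "unpaired")
  expect_equal(got2$n_subjects, 9)
})

test_that("simple effects are the paired Post-Pre t test with direction", {
  fr <- make_frame(n_per_group = 10, seed = 11)
  # Post == Pre: t = 0, n.s.
  fr_eq <- fr
  fr_eq$value[fr_eq$session == "Post"] <- fr_eq$value[fr_eq$session == "Pre"]
  se <- simple_effects(fr_eq, "MT")
  expect_equal(se$t, 0)
  expect_equal(se$direction, "n.s.")
  # Post = Pre + 1 exactly: zero within-pair variance flag
  fr_c <- fr
  fr_c$value[fr_c$session == "Post"] <- fr_c$value[fr_c$session == "Pre"] + 1
  se_c <- simple_effects(fr_c, "MT")
  expect_match(se_c$direction, "zero within-pair variance")
  expect_equal(se_c$trend, "up")
  # random paired data: equals the one-sample t on differences
  se_r <- simple_effects(fr, "RT")
  pre <- fr$value[fr$session == "Pre" & fr$group == "RT"]
  post <- fr$value[fr$session == "Post" & fr$group == "RT"]
  or <- t.test(post - pre)
  expect_equal(se_r$t, unname(or$statistic), tolerance = 1e-12)
  expect_equal(se_r$p, or$p.value, tolerance = 1e-12)
})

test_that("threshold policies implement the 1/N and fixed nodal rules", {
  pol <- threshold_policy("global", n_tests = 8)
  expect_equal(pol$alpha, 1 / 8)
  pol_n <- threshold_policy("nodal", n_tests = 1024)
  expect_equal(pol_n$alpha, 0.005)
  expect_message(threshold_policy("global", n_tests = 1), "degenerate")
  frs <- lapply(c(20, 21, 22), function(s)
    mixed_anova(make_frame(n_per_group = 6, seed = s,
                           mt_post_shift = c(0, 0, 5)[s - 19])))
  flags <- apply_threshold(frs, threshold_policy("intermediate", n_tests = 3))
  expect_length(flags, 3)
  expect_true(flags[3])                  # the planted large shift is caught
  rep_tab <- stats_report(setNames(frs, c("a", "b", "c")),
                          threshold_policy("intermediate", n_tests = 3))
  expect_equal(nrow(rep_tab), 3)
  expect_true(all(c("F_interaction", "alpha_applied", "significant",
                    "MT_direction") %in% names(rep_tab)))
})
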
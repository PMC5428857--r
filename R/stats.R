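#' Two-sample t test from summary statistics
#'
#' Pooled-variance two-sample t with `df = n1 + n2 - 2` and two-sided p,
#' for comparing groups when only means, SDs and counts are reported
#' (e.g. demographic baseline tables).
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  tval <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df))
}

#' Pearson chi-square test of a 2 x 2 table
#'
#' Pearson chi-square without continuity correction,
#' `sum((obs - exp)^2 / exp)` over the four cells, df = 1; used for
#' baseline comparisons of nominal measures such as gender counts.
#'
#' @param a,b first row counts (group 1: e.g. female, male).
#' @param c,d second row counts (group 2).
#' @return list with `X2`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all table marginals must be positive")
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  x2 <- sum((tab - expd)^2 / expd)
  list(X2 = x2, df = 1L, p = pchisq(x2, df = 1, lower.tail = FALSE))
}

#' Build a long metric frame
#'
#' Canonical long format for one metric across the cohort: one row per
#' subject-session with columns `subject_id`, `group`, `session`, `value`,
#' plus optional subject-level covariate columns (e.g. `age`, `gender`,
#' `education`).
#'
#' @param subject_id,group,session,value vectors of equal length.
#' @param covariates optional data.frame of covariate columns, same length.
#' @return data.frame of class `long_metric_frame`.
#' @export
long_metric_frame <- function(subject_id, group, session, value,
                              covariates = NULL) {
  df <- data.frame(subject_id = as.character(subject_id),
                   group = as.character(group),
                   session = as.character(session),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (!all(df$group %in% c("MT", "RT"))) stop("group must be MT or RT")
  if (!all(df$session %in% c("Pre", "Post"))) stop("session must be Pre or Post")
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  class(df) <- c("long_metric_frame", "data.frame")
  df
}

# reshape the long frame to one row per subject: group, covariates,
# subject mean m = (Pre + Post)/2 and difference d = Post - Pre; drops
# (with warning) subjects lacking a complete Pre/Post pair
subject_level <- function(frame, covariate_names = NULL) {
  pre <- frame[frame$session == "Pre", ]
  post <- frame[frame$session == "Post", ]
  ids <- intersect(pre$subject_id, post$subject_id)
  dropped <- setdiff(unique(frame$subject_id), ids)
  if (length(dropped))
    warning("dropping unpaired subject(s): ", paste(dropped, collapse = ", "))
  pre <- pre[match(ids, pre$subject_id), ]
  post <- post[match(ids, post$subject_id), ]
  out <- data.frame(subject_id = ids, group = pre$group,
                    m = (pre$value + post$value) / 2,
                    d = post$value - pre$value,
                    stringsAsFactors = FALSE)
  for (cv in covariate_names) out[[cv]] <- pre[[cv]]
  out
}

#' Two-group by two-session mixed ANOVA (optionally covariate-adjusted)
#'
#' Fits the 2 (group, between) x 2 (session, within) mixed model by its
#' exact two-stage decomposition for two time points: the group main
#' effect is tested in a between-subject model on subject means, and the
#' time main effect and group-by-time interaction are tested in a model on
#' the within-subject Post - Pre differences. With covariates on,
#' time-invariant covariates enter both models centred (numeric) or
#' effect-coded +/-0.5 (two-level factors such as gender), and group is
#' effect-coded so the time effect is the unweighted average over groups.
#' Partial eta-squared per effect is `SS_effect / (SS_effect + SS_error)`.
#'
#' @param frame a [long_metric_frame()] (or compatible data.frame).
#' @param covariates `"off"` (default) or `"on"`; when on, every column of
#'   `frame` beyond subject_id/group/session/value is used.
#' @return object of class `anova_result` with per-effect F, df, p and
#'   partial eta-squared, plus per-group simple-effect tests (paired t of
#'   Post vs Pre, see [simple_effects()]).
#' @export
mixed_anova <- function(frame, covariates = c("off", "on")) {
  covariates <- match.arg(covariates)
  cov_names <- setdiff(names(frame),
                       c("subject_id", "group", "session", "value"))
  if (covariates == "off") cov_names <- character()
  sl <- subject_level(frame, cov_names)
  if (min(table(sl$group)) < 3L)
    stop("need at least 3 paired subjects per group")
  degenerate <- var(frame$value) == 0
  X_cov <- NULL
  if (length(cov_names)) {
    X_cov <- sapply(cov_names, function(cv) {
      x <- sl[[cv]]
      if (is.numeric(x)) x - mean(x)
      else {
        lv <- sort(unique(as.character(x)))
        if (length(lv) != 2L)
          stop("covariate ", cv, " must be numeric or two-level")
        ifelse(as.character(x) == lv[2], 0.5, -0.5)
      }
    })
    X_cov <- as.matrix(X_cov)
  }
  g <- ifelse(sl$group == "MT", 0.5, -0.5)
  eff <- function(y, test_col) {
    # F test of one column of the design [1 | g | X_cov] via extra SS
    X_full <- cbind(1, g, X_cov)
    fit_full <- lm.fit(X_full, y)
    ss_err <- sum(fit_full$residuals^2)
    df_err <- length(y) - ncol(X_full)
    X_red <- X_full[, -test_col, drop = FALSE]
    ss_eff <- sum(lm.fit(X_red, y)$residuals^2) - ss_err
    f <- (ss_eff / 1) / (ss_err / df_err)
    list(F = f, df1 = 1L, df2 = df_err,
         p = pf(f, 1, df_err, lower.tail = FALSE),
         eta_sq_partial = ss_eff / (ss_eff + ss_err))
  }
  if (degenerate) {
    flat <- list(F = NA_real_, df1 = 1L, df2 = NA_integer_, p = NA_real_,
                 eta_sq_partial = NA_real_)
    res <- list(group = flat, time = flat, interaction = flat,
                degenerate = TRUE)
  } else {
    res <- list(
      group = eff(sl$m, 2L),          # between model on subject means
      time = eff(sl$d, 1L),           # intercept of the difference model
      interaction = eff(sl$d, 2L),    # group effect on differences
      degenerate = FALSE
    )
  }
  paired <- frame[frame$subject_id %in% sl$subject_id, ]
  res$simple_effects <- list(MT = simple_effects(paired, "MT"),
                             RT = simple_effects(paired, "RT"))
  res$n_subjects <- nrow(sl)
  res$covariates <- if (length(cov_names)) cov_names else "none"
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("mixed ANOVA: degenerate (zero-variance metric)\n")
    return(invisible(x))
  }
  fmt <- function(e, nm)
    cat(sprintf("  %-12s F(%d, %d) = %6.3f, p = %.4f, partial eta^2 = %.3f\n",
                nm, e$df1, e$df2, e$F, e$p, e$eta_sq_partial))
  cat(sprintf("mixed 2x2 ANOVA (%d subjects, covariates: %s)\n",
              x$n_subjects, paste(x$covariates, collapse = ", ")))
  fmt(x$group, "Group"); fmt(x$time, "Time"); fmt(x$interaction, "Group:Time")
  for (g in c("MT", "RT")) {
    se <- x$simple_effects[[g]]
    cat(sprintf("  %s Post-Pre: t(%d) = %6.3f, p = %.4f, direction %s\n",
                g, se$df, se$t, se$p, se$direction))
  }
  invisible(x)
}

#' Within-group simple effect (paired Post vs Pre t test)
#'
#' @param frame a [long_metric_frame()].
#' @param group `"MT"` or `"RT"`.
#' @param alpha significance level for calling a direction (default 0.05,
#'   uncorrected).
#' @return list with `t`, `df`, `p`, `mean_diff`, `direction` (`"up"`,
#'   `"down"` when significant at `alpha`, else `"n.s."`), and `trend`
#'   (sign of the mean change regardless of significance).
#' @export
simple_effects <- function(frame, group, alpha = 0.05) {
  sub <- frame[frame$group == group, ]
  sl <- subject_level(sub)
  if (nrow(sl) < 3L) stop("need at least 3 paired observations in ", group)
  d <- sl$d
  md <- mean(d)
  if (sd(d) <= 1e-12 * max(abs(d), 1)) {
    if (max(abs(d)) == 0)
      return(list(t = 0, df = nrow(sl) - 1L, p = 1, mean_diff = 0,
                  direction = "n.s.", trend = "flat"))
    return(list(t = NA_real_, df = nrow(sl) - 1L, p = NA_real_,
                mean_diff = md,
                direction = "flagged: zero within-pair variance",
                trend = if (md > 0) "up" else "down"))
  }
  tval <- md / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1L
  p <- 2 * pt(-abs(tval), df)
  list(t = tval, df = df, p = p, mean_diff = md,
       direction = if (p < alpha && md > 0) "up"
       else if (p < alpha && md < 0) "down" else "n.s.",
       trend = if (md > 0) "up" else if (md < 0) "down" else "flat")
}

#' Significance threshold policy for one analysis level
#'
#' The global and intermediate levels use the lenient false-positive
#' correction `alpha = 1 / n_tests`; the nodal level uses a fixed
#' uncorrected threshold (0.005 by default).
#'
#' @param level `"global"`, `"intermediate"` or `"nodal"`.
#' @param n_tests number of tests run at this level.
#' @param rule `"one_over_n"` or `"fixed"`; defaults to `one_over_n` for
#'   global/intermediate and `fixed` for nodal.
#' @param alpha the fixed threshold (used when `rule = "fixed"`).
#' @return list of class `threshold_policy` with the resolved `alpha`.
#' @export
threshold_policy <- function(level = c("global", "intermediate", "nodal"),
                             n_tests, rule = NULL, alpha = 0.005) {
  level <- match.arg(level)
  if (n_tests < 1L) stop("n_tests must be >= 1")
  if (is.null(rule)) rule <- if (level == "nodal") "fixed" else "one_over_n"
  rule <- match.arg(rule, c("one_over_n", "fixed"))
  a <- if (rule == "one_over_n") 1 / n_tests else alpha
  if (a >= 1)
    message("threshold policy degenerate: alpha = ", a,
            " flags every result")
  structure(list(level = level, rule = rule, alpha = a,
                 n_tests = as.integer(n_tests)),
            class = "threshold_policy")
}

#' Apply a threshold policy to a set of ANOVA results
#'
#' Flags each result as significant iff its interaction p value falls
#' below the policy's alpha.
#'
#' @param results list of `anova_result` objects (typically one per metric,
#'   module or node).
#' @param policy a [threshold_policy()].
#' @return logical vector, one flag per result (NA for degenerate results).
#' @export
apply_threshold <- function(results, policy) {
  stopifnot(inherits(policy, "threshold_policy"))
  vapply(results, function(r) {
    p <- r$interaction$p
    if (is.na(p)) NA else p < policy$alpha
  }, logical(1))
}

#' Tabulate ANOVA results as a stats report
#'
#' One row per tested quantity with the F/df/p of each effect, the
#' interaction effect size, the applied threshold, the significance flag
#' and the per-group Post-Pre trends.
#'
#' @param results named list of `anova_result`s.
#' @param policy a [threshold_policy()].
#' @return data.frame (the on-disk StatsReport layout).
#' @export
stats_report <- function(results, policy) {
  flags <- apply_threshold(results, policy)
  rows <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    data.frame(
      metric = names(results)[k], level = policy$level,
      F_group = r$group$F, F_time = r$time$F,
      F_interaction = r$interaction$F,
      df1 = r$interaction$df1, df2 = r$interaction$df2,
      p_interaction = r$interaction$p,
      eta_interaction = r$interaction$eta_sq_partial,
      alpha_applied = policy$alpha, significant = flags[k],
      MT_direction = r$simple_effects$MT$trend,
      MT_p = r$simple_effects$MT$p,
      RT_direction = r$simple_effects$RT$trend,
      RT_p = r$simple_effects$RT$p,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
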
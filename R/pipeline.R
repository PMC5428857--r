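#' Derive the reference modular partition from pre-session data
#'
#' Averages the thresholded networks of all pre-training scans (both
#' groups pooled by default, matching the idea of one representative
#' modular solution for the whole sample), extracts the locally significant
#' backbone, and partitions it with the spectral modularity algorithm. The
#' backbone is used only when it is informative: if the local-significance
#' filter retains no edge at the requested alpha (in near-regular networks
#' the minimum attainable local p value is 1/degree, so moderate-degree
#' networks yield nothing) or strands some node with no incident backbone
#' edge, the partition falls back to the group-mean network itself and the
#' fallback is recorded in the returned object.
#'
#' @param networks named list of `conn_result`s for the Pre session.
#' @param backbone_alpha local significance level for the backbone.
#' @return a `module_partition` with extra fields `backbone_used`
#'   (logical) and `group_mean` (the `group_mean_network`).
#' @export
derive_group_partition <- function(networks, backbone_alpha = 0.05) {
  gm <- group_mean(networks)
  backbone_used <- TRUE
  gm2 <- tryCatch(backbone_extract(gm, alpha = backbone_alpha),
                  error = function(e) {
                    backbone_used <<- FALSE
                    gm
                  })
  if (backbone_used && any(rowSums(gm2$backbone) == 0))
    backbone_used <- FALSE               # backbone strands isolated nodes
  target <- if (backbone_used) gm2$mean_w * gm2$backbone else gm$mean_w
  part <- spectral_partition(target)
  part$backbone_used <- backbone_used
  part$group_mean <- if (backbone_used) gm2 else gm
  part
}

#' Compute the three-level metric tables for a cohort of networks
#'
#' @param networks named list of `conn_result`s (all subjects, both
#'   sessions), with names `<subject>_<session>`.
#' @param meta data.frame with columns `subject_id`, `group`, `session`
#'   aligned with `networks`.
#' @param partition the reference `module_partition`.
#' @return list of long data.frames: `global` (metric column per global
#'   measure), `modules` (intra/inter strengths), `nodal` (strength per
#'   node), each with subject_id/group/session keys.
#' @export
metric_tables <- function(networks, meta, partition) {
  stopifnot(length(networks) == nrow(meta))
  n_mod <- partition$n_modules
  mods <- seq_len(n_mod)
  pairs <- if (n_mod > 1) utils::combn(mods, 2) else matrix(nrow = 2, ncol = 0)
  glo <- list(); mod <- list(); nod <- list()
  for (k in seq_along(networks)) {
    w <- adjacency(networks[[k]])
    key <- meta[k, c("subject_id", "group", "session")]
    glo[[k]] <- cbind(key, global_metrics(w), row.names = NULL)
    # singleton modules have no within-module pair: value flagged as NA
    intra <- vapply(mods, function(s)
      tryCatch(intra_module_strength(w, partition, s),
               error = function(e) NA_real_), numeric(1))
    inter <- if (ncol(pairs)) apply(pairs, 2, function(st)
      inter_module_strength(w, partition, st[1], st[2])) else numeric(0)
    mod[[k]] <- cbind(key, data.frame(
      metric = c(sprintf("intra_M%d", mods),
                 if (ncol(pairs)) sprintf("inter_M%d_M%d", pairs[1, ], pairs[2, ])),
      value = c(intra, inter)), row.names = NULL)
    S_i <- net_strength(w)$S_i
    nod[[k]] <- cbind(key, data.frame(node = partition$roi_labels,
                                      value = as.numeric(S_i)),
                      row.names = NULL)
  }
  list(global = do.call(rbind, glo), modules = do.call(rbind, mod),
       nodal = do.call(rbind, nod))
}

# run the mixed ANOVA for every column/metric of a long table
anova_per_metric <- function(tab, value_cols, covariates = "off") {
  res <- list()
  for (vc in value_cols) {
    frame <- long_metric_frame(tab$subject_id, tab$group, tab$session,
                               tab[[vc]])
    res[[vc]] <- tryCatch(mixed_anova(frame, covariates = covariates),
                          error = function(e) NULL)
  }
  res[!vapply(res, is.null, logical(1))]
}

#' Run the full longitudinal network study
#'
#' End-to-end pipeline: load or synthesize the cohort, clean every series,
#' build per-subject networks, derive one modular partition from the
#' pooled pre-session group mean, compute global / modular / nodal metric
#' tables for every subject-session, apply the 2 x 2 mixed ANOVA at each
#' level with that level's threshold policy, and write all artifacts under
#' the output directory. Re-running with an identical configuration and
#' seed reproduces every numeric table bit for bit.
#'
#' @param config a `run_config` from [validate_config()], a YAML path, or
#'   a plain list.
#' @return list of class `study_report`: the metric tables, the partition,
#'   the three stats reports, and the output paths.
#' @export
run_study <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  t0 <- proc.time()[["elapsed"]]
  set.seed(config$seed)

  cohort <- if (!is.null(config$input$synthetic))
    generate_cohort(config$input$synthetic)
  else read_cohort(config$input$manifest)
  logf("stage=load n_series=%d elapsed=%.2fs", length(cohort),
       proc.time()[["elapsed"]] - t0)

  networks <- vector("list", length(cohort))
  names(networks) <- names(cohort)
  meta <- data.frame(subject_id = character(), group = character(),
                     session = character(), stringsAsFactors = FALSE)
  for (k in seq_along(cohort)) {
    ts <- cohort[[k]]
    clean <- tryCatch(
      preprocess_ts(ts, band = c(config$band$low_hz, config$band$high_hz),
                    fd_threshold = config$fd$threshold,
                    fd_radius_mm = config$fd$radius_mm,
                    rotation_units = config$motion$units,
                    scrub_mode = config$scrub$mode),
      error = function(e)
        stop("stage=preprocess subject=", ts$subject_id, " session=",
             ts$session, ": ", conditionMessage(e)))
    cp <- tryCatch(correlation_matrix(clean), error = function(e)
      stop("stage=correlation subject=", ts$subject_id, " session=",
           ts$session, ": ", conditionMessage(e)))
    networks[[k]] <- if (config$threshold$mode == "binary")
      threshold_binary(cp$r, cp$p, q = config$threshold$fdr_q)
    else threshold_weighted(cp$r, cp$p, alpha = config$threshold$alpha)
    meta <- rbind(meta, data.frame(subject_id = ts$subject_id,
                                   group = ts$group, session = ts$session,
                                   stringsAsFactors = FALSE))
    logf("stage=network subject=%s session=%s mode=%s cost=%.4f elapsed=%.2fs",
         ts$subject_id, ts$session, config$threshold$mode,
         net_cost(networks[[k]]), proc.time()[["elapsed"]] - t0)
  }

  if (config$partition$source == "fixed") {
    ptab <- read.delim(config$partition$file)
    partition <- structure(list(assignment = as.integer(ptab$module_id),
                                Q = NA_real_,
                                n_modules = length(unique(ptab$module_id)),
                                module_names = NULL,
                                roi_labels = as.character(ptab$node_label)),
                           class = "module_partition")
    partition$backbone_used <- NA
  } else {
    pre_idx <- which(meta$session == "Pre")
    partition <- derive_group_partition(networks[pre_idx],
                                        backbone_alpha = config$partition$backbone_alpha)
    logf("stage=partition n_modules=%d Q=%.4f backbone_used=%s",
         partition$n_modules, partition$Q, partition$backbone_used)
  }

  tabs <- metric_tables(networks, meta, partition)
  logf("stage=metrics rows_global=%d rows_modules=%d rows_nodal=%d elapsed=%.2fs",
       nrow(tabs$global), nrow(tabs$modules), nrow(tabs$nodal),
       proc.time()[["elapsed"]] - t0)

  covs <- config$stats$covariates
  global_cols <- c("cost", "S_p", "E_glob", "E_loc", "L_p", "C_p",
                   "cost_efficiency", "Q")
  res_global <- anova_per_metric(tabs$global, global_cols, covs)
  pol_global <- threshold_policy("global", n_tests = length(res_global))
  rep_global <- stats_report(res_global, pol_global)

  modmetrics <- unique(tabs$modules$metric)
  res_mod <- list()
  for (mm in modmetrics) {
    sub <- tabs$modules[tabs$modules$metric == mm, ]
    frame <- long_metric_frame(sub$subject_id, sub$group, sub$session, sub$value)
    res_mod[[mm]] <- tryCatch(mixed_anova(frame, covariates = covs),
                              error = function(e) NULL)
  }
  res_mod <- res_mod[!vapply(res_mod, is.null, logical(1))]
  pol_mod <- threshold_policy("intermediate", n_tests = length(res_mod))
  rep_mod <- stats_report(res_mod, pol_mod)

  res_nod <- list()
  for (nd in partition$roi_labels) {
    sub <- tabs$nodal[tabs$nodal$node == nd, ]
    frame <- long_metric_frame(sub$subject_id, sub$group, sub$session, sub$value)
    res_nod[[nd]] <- tryCatch(mixed_anova(frame, covariates = covs),
                              error = function(e) NULL)
  }
  res_nod <- res_nod[!vapply(res_nod, is.null, logical(1))]
  pol_nod <- threshold_policy("nodal", n_tests = length(res_nod),
                              rule = "fixed",
                              alpha = config$stats$nodal_alpha)
  rep_nod <- stats_report(res_nod, pol_nod)
  logf("stage=stats alpha_global=%.4g alpha_intermediate=%.4g alpha_nodal=%.4g df2=%d",
       pol_global$alpha, pol_mod$alpha, pol_nod$alpha,
       if (length(res_global)) res_global[[1]]$interaction$df2 else NA_integer_)

  write_report_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 12, format = "g"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  paths <- c(
    write_report_tsv(tabs$global, "global_metrics.tsv"),
    write_report_tsv(tabs$modules, "module_strengths.tsv"),
    write_report_tsv(tabs$nodal, "nodal_strength.tsv"),
    write_report_tsv(rep_global, "stats_global.tsv"),
    write_report_tsv(rep_mod, "stats_intermediate.tsv"),
    write_report_tsv(rep_nod, "stats_nodal.tsv"))
  ppath <- file.path(out_dir, "partition.tsv")
  write_partition(partition, ppath)
  paths <- c(paths, ppath)
  prov <- c(sprintf("seed: %d", config$seed),
            sprintf("threshold_mode: %s", config$threshold$mode),
            sprintf("partition_source: %s", config$partition$source),
            sprintf("backbone_used: %s", partition$backbone_used),
            sprintf("config_sha: %s", config_hash(config)),
            sprintf("package_version: %s",
                    as.character(utils::packageVersion("longnet"))))
  writeLines(prov, file.path(out_dir, "provenance.txt"))
  paths <- c(paths, file.path(out_dir, "provenance.txt"))
  logf("stage=done elapsed=%.2fs", proc.time()[["elapsed"]] - t0)

  structure(list(tables = tabs, partition = partition,
                 stats = list(global = rep_global, intermediate = rep_mod,
                              nodal = rep_nod),
                 policies = list(global = pol_global, intermediate = pol_mod,
                                 nodal = pol_nod),
                 paths = paths, out_dir = out_dir),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("longitudinal network study report\n")
  cat(sprintf("  partition: %d modules, Q = %.4f\n",
              x$partition$n_modules, x$partition$Q))
  for (lev in names(x$stats)) {
    st <- x$stats[[lev]]
    cat(sprintf("  %s: %d tests, alpha = %.4g, %d significant interaction(s)\n",
                lev, nrow(st), x$policies[[lev]]$alpha,
                sum(st$significant, na.rm = TRUE)))
  }
  cat("  outputs in:", x$out_dir, "\n")
  invisible(x)
}

# deterministic hash of the analysis configuration (file-content based);
# the output location is excluded so identical analyses hash identically
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  config <- unclass(config)
  config$output <- NULL
  plain <- rapply(config, function(x)
    if (inherits(x, "cohort_spec")) unclass(x) else x, how = "replace")
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}
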
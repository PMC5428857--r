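# known configuration keys (dotted paths) and their defaults
config_defaults <- function() {
  list(
    input = list(synthetic = NULL, manifest = NULL),
    band = list(low_hz = 0.01, high_hz = 0.1),
    fd = list(threshold = 1, radius_mm = 50),
    motion = list(units = "radians"),
    gsr = list(enabled = FALSE),
    scrub = list(mode = "censor"),
    threshold = list(mode = "weighted", alpha = 0.05, fdr_q = 0.01),
    partition = list(source = "pretest_group_mean", file = NULL,
                     per_group = FALSE, backbone_alpha = 0.05),
    stats = list(covariates = "off", nodal_alpha = 0.005,
                 simple_effects_alpha = 0.05),
    output = list(dir = "longnet_report"),
    seed = 1L
  )
}

flatten_keys <- function(x, prefix = character()) {
  out <- character()
  for (nm in names(x)) {
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.list(x[[nm]]) && !is.null(names(x[[nm]])) && length(x[[nm]]) > 0 &&
        !nm %in% c("synthetic", "delta_intra", "delta_inter"))
      out <- c(out, flatten_keys(x[[nm]], c(prefix, nm)))
    else out <- c(out, key)
  }
  out
}

#' Validate a run configuration
#'
#' Parses a YAML run configuration (or an equivalent R list), fills
#' documented defaults, and returns either the completed configuration or
#' the full list of violations -- every problem is reported, not just the
#' first. Unknown keys are reported with a nearest-match suggestion.
#'
#' @param config path to a YAML file, or a named list.
#' @return list of class `run_config` on success; otherwise an error whose
#'   message enumerates all violations.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML mapping or a list")
  defaults <- config_defaults()
  errors <- character()
  known <- flatten_keys(defaults)
  supplied <- flatten_keys(config)
  for (key in supplied) {
    root <- strsplit(key, ".", fixed = TRUE)[[1]][1]
    if (!key %in% known && !root %in% names(defaults)) {
      near <- known[which.min(utils::adist(key, known))]
      errors <- c(errors, sprintf("unknown key '%s' (did you mean '%s'?)",
                                  key, near))
    }
  }
  cfg <- modifyList(defaults, config[names(config) %in% names(defaults)])
  has_syn <- !is.null(cfg$input$synthetic)
  has_man <- !is.null(cfg$input$manifest)
  if (has_syn && has_man)
    errors <- c(errors, "exactly one input source allowed: both input.synthetic and input.manifest are set")
  if (!has_syn && !has_man)
    errors <- c(errors, "no input source: set input.synthetic or input.manifest")
  if (has_man && !file.exists(cfg$input$manifest)) {
    errors <- c(errors, paste0("input.manifest does not exist: ", cfg$input$manifest))
  } else if (has_man) {
    man <- tryCatch(read.delim(cfg$input$manifest, stringsAsFactors = FALSE),
                    error = function(e) NULL)
    if (is.null(man) || !"timeseries_path" %in% names(man)) {
      errors <- c(errors, "input.manifest is not a readable manifest TSV")
    } else {
      refs <- c(man$timeseries_path,
                if ("motion_path" %in% names(man))
                  man$motion_path[nzchar(man$motion_path) &
                                    !is.na(man$motion_path)])
      missing <- refs[!file.exists(file.path(dirname(cfg$input$manifest), refs))]
      for (f in missing)
        errors <- c(errors, paste0("manifest references a missing file: ", f))
    }
  }
  if (cfg$band$low_hz >= cfg$band$high_hz)
    errors <- c(errors, sprintf("band.low_hz (%g) must be below band.high_hz (%g)",
                                cfg$band$low_hz, cfg$band$high_hz))
  if (cfg$fd$threshold <= 0)
    errors <- c(errors, "fd.threshold must be positive")
  if (!cfg$threshold$mode %in% c("weighted", "binary"))
    errors <- c(errors, "threshold.mode must be 'weighted' or 'binary'")
  if (!cfg$scrub$mode %in% c("censor", "spike"))
    errors <- c(errors, "scrub.mode must be 'censor' or 'spike'")
  if (!cfg$motion$units %in% c("radians", "degrees"))
    errors <- c(errors, "motion.units must be 'radians' or 'degrees'")
  if (!cfg$partition$source %in% c("pretest_group_mean", "fixed"))
    errors <- c(errors, "partition.source must be 'pretest_group_mean' or 'fixed'")
  if (cfg$partition$source == "fixed" &&
      (is.null(cfg$partition$file) || !file.exists(cfg$partition$file)))
    errors <- c(errors, "partition.source = fixed requires an existing partition.file")
  if (!cfg$stats$covariates %in% c("on", "off"))
    errors <- c(errors, "stats.covariates must be 'on' or 'off'")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  if (has_syn && !inherits(cfg$input$synthetic, "cohort_spec"))
    cfg$input$synthetic <- do.call(cohort_spec, cfg$input$synthetic)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}
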
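# Pipeline orchestration and command-line entry points: simulate ->
# extract-features -> cluster / classify / survival, driven by a JSON
# config, with machine-readable JSON summaries per stage.

#' Load and validate a run configuration
#'
#' The configuration is a JSON object; recognized keys (all optional
#' unless a stage needs them): `cell_tables_dir`, `survival_table`,
#' `output_dir`, `hierarchy_file`, `radii`, `n_null`, `grid_dim`,
#' `window` (`[xmin, xmax, ymin, ymax]`), `padding`, `center`,
#' `mad_constant`, `seed`, `k_min`, `k_max`, `n_runs`, `n_trees`,
#' `n_perm`, `efs_cutoff`, `survival_k`.
#'
#' @param config Path to a JSON file, or an equivalent named list.
#' @return Validated config list (class `run_config`) with defaults
#'   filled in and a `config_hash` field.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config))
    jsonlite::read_json(config, simplifyVector = TRUE) else config
  defaults <- list(radii = c(5, 10, 25, 50, 75, 100), n_null = 199,
                   grid_dim = c(100, 100), padding = 0,
                   center = "theoretical", mad_constant = 1, seed = 1,
                   k_min = 2, k_max = 5, n_runs = 20, n_trees = 100000,
                   n_perm = 10, efs_cutoff = 12, survival_k = 2,
                   output_dir = ".")
  for (k in names(defaults)) cfg[[k]] <- cfg[[k]] %||% defaults[[k]]
  for (k in c("cell_tables_dir", "survival_table", "hierarchy_file"))
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop_("config path does not exist: %s = %s", k, cfg[[k]])
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  cfg$config_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(cfg, class = "run_config")
}

.cfg_hierarchy <- function(cfg) {
  if (!is.null(cfg$hierarchy_file)) read_hierarchy(cfg$hierarchy_file)
  else default_hierarchy()
}

.cfg_window <- function(cfg) {
  if (is.null(cfg$window)) NULL
  else tme_window(cfg$window[1], cfg$window[2], cfg$window[3],
                  cfg$window[4])
}

#' Run feature extraction over a directory of cell tables
#'
#' Parses every `*.csv` under `cell_tables_dir`, splits regions, extracts
#' the full feature schema per region, aggregates to patient level per
#' region class, filters by missingness and imputes, and writes
#' `features_<class>.tsv` (+ JSON sidecars) into `output_dir`.
#'
#' @param config A [run_config()] (or path/list coercible to one).
#' @return Named list of filtered patient x feature matrices, invisibly.
#' @export
run_extract <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(cfg$cell_tables_dir)) stop_("config needs cell_tables_dir")
  files <- sort(list.files(cfg$cell_tables_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files))
    stop_("no .csv cell tables in %s", cfg$cell_tables_dir)
  hierarchy <- .cfg_hierarchy(cfg)
  win <- .cfg_window(cfg)
  ncfg <- null_config(n_null = cfg$n_null, grid_dim = cfg$grid_dim,
                      seed = cfg$seed, center = cfg$center,
                      mad_constant = cfg$mad_constant,
                      cache = new.env(parent = emptyenv()))
  feats <- list()
  for (f in files) {
    cells <- parse_cell_table(f)
    if (nrow(cells) == 0L) next
    pats <- split_regions(cells, hierarchy, window = win,
                          padding = cfg$padding)
    for (p in pats) {
      t0 <- proc.time()[["elapsed"]]
      fx <- extract_region_features(p, hierarchy, cfg$radii, ncfg)
      message(sprintf("extracted %s (%s): %d cells, %d features, %.1fs",
                      p$region_id, p$region_class, p$n_total, nrow(fx),
                      proc.time()[["elapsed"]] - t0))
      feats[[length(feats) + 1L]] <- fx
    }
  }
  mats <- aggregate_patient_features(feats)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (cl in names(mats)) {
    filt <- filter_and_impute(mats[[cl]])
    write_feature_matrix(
      filt, file.path(cfg$output_dir, sprintf("features_%s.tsv", cl)),
      extra = list(region_class = cl, config_hash = cfg$config_hash))
    out[[cl]] <- filt
  }
  invisible(out)
}

#' Run the downstream analyses on an extracted feature matrix
#'
#' Consensus NMF clustering over K = `k_min`..`k_max`, random-forest
#' classification of the dichotomized outcome with permutation
#' importances, and Kaplan-Meier/log-rank comparison of the consensus
#' clusters at `survival_k`. Writes `clusters.tsv`, `consensus_K*.tsv`,
#' and `analysis.json` into `output_dir`.
#'
#' @param config A [run_config()].
#' @param features Patient x feature matrix; defaults to
#'   `features_tumor.tsv` in `output_dir`.
#' @param only Optional subset of stages: any of `"cluster"`,
#'   `"classify"`, `"survival"`.
#' @return List of stage results, invisibly.
#' @export
run_analyze <- function(config, features = NULL,
                        only = c("cluster", "classify", "survival")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  only <- match.arg(only, several.ok = TRUE)
  if (is.null(features)) {
    fp <- file.path(cfg$output_dir, "features_tumor.tsv")
    if (!file.exists(fp)) stop_("feature matrix not found: %s", fp)
    features <- read_feature_matrix(fp)
  }
  res <- list()
  report <- list(config_hash = cfg$config_hash)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

  surv <- NULL
  if (!is.null(cfg$survival_table)) {
    surv <- utils::read.delim(cfg$survival_table, stringsAsFactors = FALSE)
    unmatched <- setdiff(rownames(features), surv$patient_id)
    if (length(unmatched) && any(c("classify", "survival") %in% only))
      stop_("patients missing from survival table: %s",
            paste(unmatched, collapse = ", "))
  }

  if ("cluster" %in% only) {
    V <- nmf_preprocess(t(features))
    cc <- consensus_cluster(V, k_range = cfg$k_min:cfg$k_max,
                            n_runs = cfg$n_runs, seed = cfg$seed)
    res$cluster <- cc
    lab_df <- data.frame(patient_id = rownames(features))
    for (k in names(cc)) {
      lab_df[[paste0("K", k)]] <- unname(cc[[k]]$labels[rownames(features)])
      utils::write.table(
        cc[[k]]$consensus,
        file.path(cfg$output_dir, sprintf("consensus_K%s.tsv", k)),
        sep = "\t", quote = FALSE)
    }
    utils::write.table(lab_df, file.path(cfg$output_dir, "clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    report$cluster <- lapply(cc, function(r)
      list(k = r$k, cophenetic = r$cophenetic,
           top_features = r$top_features))
  }

  if ("classify" %in% only) {
    if (is.null(surv)) stop_("classification needs survival_table")
    labels <- dichotomize_outcome(surv, cfg$efs_cutoff)
    rf <- rf_oob_classify(features, labels, n_trees = cfg$n_trees,
                          seed = cfg$seed)
    imp <- group_permutation_importance(rf, n_perm = cfg$n_perm,
                                        seed = cfg$seed)
    signed <- signed_feature_direction(rf$mat, rf$labels, imp)
    res$classify <- list(rf = rf, importance = imp, signed = signed)
    report$classify <- list(
      oob_auc = rf$auc, n_trees = cfg$n_trees,
      n_patients = nrow(rf$mat),
      signed_importance = as.list(signed))
  }

  if ("survival" %in% only) {
    if (is.null(surv)) stop_("survival stage needs survival_table")
    klab <- if (!is.null(res$cluster))
      res$cluster[[as.character(cfg$survival_k)]]$labels
    else hierarchical_clusters(features, cfg$survival_k)
    km <- km_logrank(klab, surv, times = c(0, 12, 24, 36, 48, 60))
    res$survival <- km
    report$survival <- list(k = cfg$survival_k, chisq = km$chisq,
                            p_value = km$p_value)
    utils::write.table(km$at_risk,
                       file.path(cfg$output_dir, "km_at_risk.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  jsonlite::write_json(report, file.path(cfg$output_dir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Simulate a cohort and write it to disk per the config
#'
#' Config keys consumed: `n_patients`, `regions_per_patient`,
#' `hazard_ratio`, `shared_fraction`, `sigma`, `seed`, `output_dir`.
#'
#' @param config A [run_config()].
#' @return The cohort, invisibly.
#' @export
run_simulate <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  cohort <- simulate_cohort(
    n_patients = cfg$n_patients %||% 40,
    regions_per_patient = cfg$regions_per_patient %||% 3,
    hazard_ratio = cfg$hazard_ratio %||% 3,
    shared_fraction = cfg$shared_fraction %||% 0.9,
    sigma = cfg$sigma %||% 15,
    seed = cfg$seed)
  write_cohort(cohort, cfg$output_dir)
  invisible(cohort)
}

#' Command-line entry point
#'
#' `tme_cli(c("<subcommand>", "--config", "cfg.json", ...))` with
#' subcommands `simulate`, `extract-features`, `cluster`, `classify`,
#' `survival`, `run-all`. Flags of the form `--key value` override config
#' entries (numeric where possible). Designed to back an Rscript wrapper:
#' see `system.file("cli", "tme.R", package = "spatialTME")`.
#'
#' @param args Character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Exit status 0 invisibly; stops with a message on bad usage.
#' @export
tme_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tme.R <simulate|extract-features|cluster|classify|survival|run-all>",
    "[--config cfg.json] [--key value ...]")
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]; args <- args[-1]
  cfg <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop_("unexpected argument '%s'\n%s", args[i], usage)
    key <- sub("^--", "", args[i])
    key <- gsub("-", "_", key)
    val <- args[i + 1L]
    if (key == "config") {
      file_cfg <- jsonlite::read_json(val, simplifyVector = TRUE)
      cfg <- utils::modifyList(file_cfg, cfg)
    } else {
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
    i <- i + 2L
  }
  cfg <- run_config(cfg)
  switch(cmd,
    "simulate" = run_simulate(cfg),
    "extract-features" = run_extract(cfg),
    "cluster" = run_analyze(cfg, only = "cluster"),
    "classify" = run_analyze(cfg, only = "classify"),
    "survival" = run_analyze(cfg, only = c("cluster", "survival")),
    "run-all" = {
      run_extract(cfg)
      run_analyze(cfg)
    },
    stop_("unknown subcommand '%s'\n%s", cmd, usage))
  invisible(0L)
}
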
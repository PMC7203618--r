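# Config-file driven workflows: the two end-to-end pipelines (fall
# prediction; imminent-precursor detection) with run manifests and artifact
# output, plus the thin command-line wrapper in inst/cli/fallrisk.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

config_section <- function(config, name) {
  sec <- config[[name]] %||% list()
  stopifnot(is.list(sec))
  sec
}

build_cfg <- function(config) {
  overrides <- config_section(config, "pipeline")
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown))
    stop("unknown pipeline settings: ", paste(unknown, collapse = ", "))
  base <- if (isTRUE(config$benchmark %||% FALSE)) benchmark_config else pipeline_config
  do.call(base, overrides)
}

load_pipeline_corpus <- function(config) {
  inp <- config_section(config, "input")
  if (!is.null(inp$corpus_dir)) {
    read_corpus(inp$corpus_dir)
  } else if (!is.null(inp$records) && !is.null(inp$patients)) {
    read_corpus(inp$records, inp$patients)
  } else if (!is.null(inp$synthetic)) {
    gen_args <- inp$synthetic
    gen_args$seed <- gen_args$seed %||% config$seed %||% 1L
    if (isTRUE(gen_args$null)) {
      gen_args$null <- NULL
      null_corpus(do.call(generator_config, gen_args))$corpus
    } else {
      do.call(generator_config, gen_args) |> generate_corpus() |> getElement("corpus")
    }
  } else {
    stop("config input section must give corpus_dir, records+patients, or synthetic")
  }
}

write_report_artifacts <- function(report, out_dir, config, cfg, elapsed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  to_num <- function(x) unname(as.numeric(x))
  report_json <- list(
    target = report$target, level = report$level,
    auc = to_num(report$auc), threshold = to_num(report$threshold),
    confusion = report$confusion[c("tp", "fp", "fn", "tn")],
    sensitivity = to_num(report$stats$sensitivity),
    sensitivity_ci = to_num(report$stats$sensitivity_ci),
    specificity = to_num(report$stats$specificity),
    specificity_ci = to_num(report$stats$specificity_ci),
    odds_ratio = to_num(report$stats$odds_ratio),
    odds_ratio_ci = to_num(report$stats$odds_ratio_ci),
    n_selected_words = length(report$selected),
    seed = report$seed
  )
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$roc$points, file.path(out_dir, "roc_points.csv"),
                   row.names = FALSE)
  if (identical(report$level, "patient")) {
    utils::write.table(report$scores, file.path(out_dir, "patient_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(report$scores, file.path(out_dir, "record_scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  s <- summary(report$fit$model)
  utils::write.table(s, file.path(out_dir, "model_weights.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("fallrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = report$seed,
    config = config,
    pipeline_settings = unclass(cfg),
    elapsed_seconds = round(elapsed, 2),
    selected_words = report$selected,
    tally_counts = as.list(report$tally[report$tally > 0]),
    mcmc = list(max_rhat = report$fit$model$max_rhat,
                converged = report$fit$model$converged)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the fall-prediction pipeline from a config file
#'
#' Executes prepare, split, embed, ensemble, select, finalize and evaluate
#' in one call, writing a run manifest, the evaluation report, ROC points,
#' patient scores and model weights under the output directory.
#'
#' @param config path to a YAML config file, or an equivalent list. Sections:
#'   `input` (one of `corpus_dir`; `records` + `patients`; or `synthetic`
#'   with [generator_config()] fields), `pipeline` (overrides for
#'   [pipeline_config()]), optional `benchmark: true` to start from
#'   [benchmark_config()], `seed`, `out`, and optional `experiments`
#'   (number of replicate seeds).
#' @param out output directory (overrides the config's `out`).
#' @return the `fall_eval_report` (or list of reports when `experiments > 1`),
#'   invisibly.
#' @export
run_fall_pipeline <- function(config, out = NULL) {
  t0 <- proc.time()["elapsed"]
  config <- read_pipeline_config(config)
  cfg <- build_cfg(config)
  out_dir <- out %||% config$out %||% stop("no output directory configured")
  seed <- as.integer(config$seed %||% 1L)
  corpus <- load_pipeline_corpus(config)
  n_exp <- as.integer(config$experiments %||% 1L)

  if (n_exp <= 1L) {
    report <- run_experiment(corpus, cfg, seed = seed)
    write_report_artifacts(report, out_dir, config, cfg,
                           proc.time()["elapsed"] - t0)
    return(invisible(report))
  }
  seeds <- seed + seq_len(n_exp) - 1L
  runs <- run_experiments(corpus, cfg, seeds = seeds)
  for (i in seq_along(runs$reports)) {
    write_report_artifacts(runs$reports[[i]],
                           file.path(out_dir, sprintf("experiment%d", i)),
                           config, cfg, proc.time()["elapsed"] - t0)
  }
  utils::write.csv(runs$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(runs$r2, file.path(out_dir, "pairwise_r2.csv"),
                   row.names = FALSE)
  invisible(runs)
}

#' Run the imminent-precursor pipeline from a config file
#'
#' As [run_fall_pipeline()] but for the record-level pre-fall precursor
#' workflow on the faller subset: tagging by the pre-fall window, optional
#' length-of-stay stratification, and record-level evaluation.
#'
#' @param config as in [run_fall_pipeline()]; additionally honours
#'   `stratum` (`"all"`, `"short"`, `"long"`) and `pipeline$imminent_window`.
#' @param out output directory override.
#' @return the `fall_eval_report`, invisibly.
#' @export
run_imminent_pipeline <- function(config, out = NULL) {
  t0 <- proc.time()["elapsed"]
  config <- read_pipeline_config(config)
  cfg <- build_cfg(config)
  out_dir <- out %||% config$out %||% stop("no output directory configured")
  seed <- as.integer(config$seed %||% 1L)
  stratum <- config$stratum %||% "all"
  corpus <- load_pipeline_corpus(config)
  report <- run_imminent_experiment(corpus, cfg, seed = seed, stratum = stratum)
  write_report_artifacts(report, out_dir, config, cfg,
                         proc.time()["elapsed"] - t0)
  invisible(report)
}
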
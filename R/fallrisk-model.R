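#' Pipeline configuration
#'
#' Collects every tunable of the fall-risk pipeline with its default:
#' embedding dimension 300, 5 negative samples, top-1000 vocabulary,
#' character-count exclusion at 50, patient-level 50/50 learning/test
#' split, 3 bisections (6 primary models), selection at 4-of-6, Normal(0, 1)
#' prior, SMOTE with 5 neighbours, and a 7-day imminent window.
#'
#' @param dim,window,epochs,negatives,top_k,min_count,smoothing embedding
#'   settings, see [embedding_config()].
#' @param min_chars record exclusion threshold (keep records with more than
#'   `min_chars` characters).
#' @param fraction learning-set fraction of the patient split.
#' @param stratify stratify splits by class.
#' @param bisections number of random bisections of the learning set.
#' @param min_models selection threshold: significant in at least this many
#'   primary models.
#' @param prior_sd prior standard deviation of the logistic weights.
#' @param level credible level of the per-model significance rule.
#' @param smote_k SMOTE neighbourhood size.
#' @param chains,warmup,iter,L_max HMC settings per fit (defaults give
#'   1000 retained draws).
#' @param imminent_window,include_fall_day pre-fall window definition.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dim = 300L, window = 5L, epochs = 20L,
                            negatives = 5L, top_k = 1000L, min_count = 1L,
                            smoothing = 0.5,
                            min_chars = 50L, fraction = 0.5, stratify = TRUE,
                            bisections = 3L, min_models = 4L,
                            prior_sd = 1, level = 0.95, smote_k = 5L,
                            chains = 2L, warmup = 300L, iter = 500L,
                            L_max = 5L,
                            imminent_window = 7L, include_fall_day = FALSE) {
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), negatives = as.integer(negatives),
                 top_k = as.integer(top_k), min_count = as.integer(min_count),
                 smoothing = smoothing,
                 min_chars = as.integer(min_chars), fraction = fraction,
                 stratify = stratify, bisections = as.integer(bisections),
                 min_models = as.integer(min_models), prior_sd = prior_sd,
                 level = level, smote_k = as.integer(smote_k),
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), L_max = as.integer(L_max),
                 imminent_window = as.integer(imminent_window),
                 include_fall_day = include_fall_day),
            class = "pipeline_config")
}

#' Reduced-size configuration for the synthetic benchmark
#'
#' The synthetic benchmark corpora are exchangeable token streams without
#' syntax, so the package's benchmark runs use a smaller embedding space and
#' fewer passes than the full-scale defaults: dimension 256 over a top-200
#' vocabulary (the rectangular context layer keeps the document-word matrix
#' full rank and well conditioned, so each word's weight is identified by
#' the data rather than pinned to the prior), window 1, 3 stochastic
#' epochs, and a single HMC chain with 1000 retained draws. These sizes are
#' the package's own benchmark choice; every methodological setting
#' (negatives, selection rule, prior, SMOTE, window) keeps its default.
#'
#' @param ... overrides forwarded to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
benchmark_config <- function(...) {
  args <- list(dim = 256L, window = 1L, epochs = 3L, top_k = 200L,
               chains = 1L, warmup = 250L, iter = 1000L, L_max = 4L)
  override <- list(...)
  args[names(override)] <- override
  do.call(pipeline_config, args)
}

as_embedding_config <- function(cfg, seed) {
  embedding_config(dim = cfg$dim, negatives = cfg$negatives, top_k = cfg$top_k,
                   window = cfg$window, epochs = cfg$epochs,
                   min_count = cfg$min_count, smoothing = cfg$smoothing,
                   seed = seed)
}

prepare_corpus <- function(corpus, cfg) {
  corpus <- integrate_daily_records(corpus)
  filter_short_records(corpus, cfg$min_chars)
}

#' Fit the fall-risk model
#'
#' End-to-end fit on a learning corpus: same-day integration and short-record
#' exclusion, top-k vocabulary, joint word/document embedding, document-word
#' matrix, bisection ensemble with per-model significance voting, stable
#' vocabulary selection, and the final trimmed Bayesian logistic model.
#'
#' @param corpus the learning `nursing_corpus` (tokenized).
#' @param cfg a [pipeline_config()].
#' @param target `"faller"` for fall prediction (record labels inherited
#'   from the patient's case-control status) or `"imminent"` for pre-fall
#'   precursor detection (requires [tag_imminent()] tags; applied
#'   automatically to an untagged faller-only corpus).
#' @param seed integer seed; the whole fit is deterministic given the seed.
#' @param allow_empty when no word is stable across the ensemble, return a
#'   chance-level model (every probability 0.5) with a warning instead of
#'   erroring. Experiment drivers enable this so null calibrations remain
#'   evaluable.
#' @return an object of class `fall_risk_model` with components
#'   `vocabulary` (full top-k vocabulary), `tally` (ensemble votes),
#'   `selected` (stable vocabulary), `model` (final
#'   `logistic_risk_model`), `W` (word matrix with frozen output layer),
#'   `config`, `target`, `seed`.
#' @seealso [predict.fall_risk_model()], [run_experiment()]
#' @export
fit_fall_risk <- function(corpus, cfg = pipeline_config(),
                          target = c("faller", "imminent"), seed = 1L,
                          allow_empty = FALSE) {
  target <- match.arg(target)
  stopifnot(inherits(corpus, "nursing_corpus"))
  corpus <- prepare_corpus(corpus, cfg)
  if (target == "imminent" && all(corpus$records$imminent == "untagged"))
    corpus <- tag_imminent(corpus, cfg$imminent_window, cfg$include_fall_day)

  seeds <- derive_seeds(seed, 3L)
  vocab <- build_vocabulary(corpus, cfg$top_k, cfg$min_count)
  emb <- train_embeddings(corpus, vocab, as_embedding_config(cfg, seeds[1]))
  dw <- compute_dw(emb$D, emb$W)

  tally <- run_bisection_ensemble(corpus, cfg, target = target,
                                  seed = seeds[2], dw = dw)
  selected <- select_vocabulary(tally, cfg$min_models)
  if (!length(selected)) {
    if (!allow_empty)
      stop("no word was significant in at least ", cfg$min_models,
           " primary models; no final model can be built")
    warning("no stable vocabulary; returning a chance-level model")
    model <- NULL
  } else {
    model <- build_final_model(corpus, selected, cfg, target = target,
                               seed = seeds[3], dw = dw)
  }

  structure(list(vocabulary = vocab, tally = tally, selected = selected,
                 model = model, W = emb$W, config = cfg, target = target,
                 seed = seed,
                 n_records = nrow(corpus$records),
                 n_patients = nrow(corpus$patients)),
            class = "fall_risk_model")
}

#' @export
print.fall_risk_model <- function(x, ...) {
  cat("Fall-risk model (", x$target, " target)\n", sep = "")
  cat(sprintf("  learning corpus: %d patients / %d records\n",
              x$n_patients, x$n_records))
  cat(sprintf("  vocabulary: %d words; selected (>= %d of %d models): %d\n",
              nrow(x$vocabulary), x$config$min_models,
              attr(x$tally, "n_models"), length(x$selected)))
  if (is.null(x$model))
    cat("  final model: chance-level (no stable vocabulary)\n")
  else
    cat(sprintf("  final model: %d weights, max split R-hat %.3f\n",
                length(x$model$coefficients), x$model$max_rhat))
  invisible(x)
}

#' @export
coef.fall_risk_model <- function(object, ...) coef(object$model)

#' @export
summary.fall_risk_model <- function(object, n = 10L, ...) {
  s <- summary(object$model)
  s <- s[s$term != "(Intercept)", ]
  s <- s[order(-abs(s$estimate)), ]
  cat("Top", min(n, nrow(s)), "selected words by |posterior mean|\n")
  print(utils::head(s, n), digits = 3, row.names = FALSE)
  invisible(s)
}

#' @export
plot.fall_risk_model <- function(x, n = 20L, ...) {
  s <- summary(x$model)
  s <- s[s$term != "(Intercept)", ]
  s <- utils::head(s[order(-abs(s$estimate)), ], n)
  old <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(old))
  idx <- rev(seq_len(nrow(s)))
  plot(s$estimate, idx, xlim = range(s$lower, s$upper), yaxt = "n",
       xlab = "posterior weight", ylab = "", pch = 16,
       main = "Strongest vocabulary weights", ...)
  graphics::segments(s$lower, idx, s$upper, idx)
  graphics::abline(v = 0, lty = 3)
  graphics::axis(2, at = idx, labels = s$term, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Score new records with a fitted fall-risk model
#'
#' Prepares the new corpus with the model's own exclusion settings, infers
#' document vectors against the frozen embedding, forms the document-word
#' matrix restricted to the selected vocabulary, and applies the final
#' logistic model. Patient-level scores are the per-patient means of the
#' record probabilities.
#'
#' @param object a `fall_risk_model`.
#' @param corpus a tokenized `nursing_corpus` of unseen records.
#' @param type `"record"` for per-record probabilities, `"patient"` for
#'   aggregated patient risk scores.
#' @param seed seed of the (deterministic) inference pass.
#' @param ... unused.
#' @return for `type = "record"` a data.frame `patient_id`, `date`,
#'   `probability` (plus the record label implied by the model target); for
#'   `type = "patient"` a `patient_risk_scores` data.frame.
#' @export
predict.fall_risk_model <- function(object, corpus,
                                    type = c("record", "patient"),
                                    seed = NULL, ...) {
  type <- match.arg(type)
  stopifnot(inherits(corpus, "nursing_corpus"))
  cfg <- object$config
  corpus <- prepare_corpus(corpus, cfg)
  if (object$target == "imminent" && all(corpus$records$imminent == "untagged"))
    corpus <- tag_imminent(corpus, cfg$imminent_window, cfg$include_fall_day)
  if (is.null(object$model)) {
    p <- rep(0.5, nrow(corpus$records))
  } else {
    ecfg <- as_embedding_config(cfg, seed %||% (object$seed + 1L))
    D <- infer_doc_vectors(corpus, object$vocabulary, object$W, ecfg)
    dw <- compute_dw(D, object$W)
    dw <- trim_columns(dw, object$selected)
    p <- predict_risk(object$model, dw)
  }
  rec <- data.frame(patient_id = corpus$records$patient_id,
                    date = corpus$records$date,
                    probability = unname(p),
                    stringsAsFactors = FALSE)
  if (object$target == "imminent") rec$imminent <- corpus$records$imminent
  else rec$label <- corpus$patients$label[match(rec$patient_id,
                                                corpus$patients$patient_id)]
  if (type == "record") return(rec)
  patient_scores(rec, corpus)
}

report_from_scores <- function(scores, labels = NULL) {
  curve <- roc_curve(scores, labels)
  thr <- optimal_threshold(curve)
  cm <- confusion_at(scores, thr, labels)
  stats <- confusion_stats(cm)
  list(roc = curve, auc = curve$auc, threshold = thr,
       confusion = cm, stats = stats)
}

#' Run one end-to-end fall-prediction experiment
#'
#' Splits the full corpus into learning and test halves at the patient
#' level, fits the fall-risk model on the learning half, scores the test
#' half, and evaluates: patient-level ROC/AUC, the closest-to-(0,1)
#' threshold, the confusion matrix and sensitivity/specificity/odds-ratio
#' statistics.
#'
#' @param corpus the full tokenized case-control `nursing_corpus`.
#' @param cfg a [pipeline_config()].
#' @param seed integer seed; a fixed seed reproduces the experiment exactly.
#' @return a `fall_eval_report` list: `auc`, `threshold`, `confusion`,
#'   `stats`, `scores`, `roc`, `selected`, `tally`, `fit`, `seed`.
#' @export
run_experiment <- function(corpus, cfg = pipeline_config(), seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  halves <- split_patients(corpus, cfg$fraction, seed = seeds[1],
                           stratify = cfg$stratify)
  fit <- fit_fall_risk(halves$part1, cfg, target = "faller", seed = seeds[2],
                       allow_empty = TRUE)
  scores <- predict(fit, halves$part2, type = "patient", seed = seeds[3])
  rep <- report_from_scores(scores)
  structure(c(rep, list(scores = scores, selected = fit$selected,
                        tally = fit$tally, fit = fit, seed = seed,
                        level = "patient", target = "faller")),
            class = "fall_eval_report")
}

#' Run one imminent-precursor experiment
#'
#' Record-level variant of [run_experiment()] on a faller-only corpus:
#' records are tagged by the pre-fall window, optionally restricted to a
#' length-of-stay stratum, split at the patient level, and the model is
#' trained and evaluated on the probability of each record being imminent
#' (no patient aggregation).
#'
#' @param fallers a faller-only `nursing_corpus` with fall dates.
#' @param cfg a [pipeline_config()].
#' @param seed integer seed.
#' @param stratum `"all"`, `"short"` (at most 45 records per patient) or
#'   `"long"` (more than 60).
#' @return a `fall_eval_report` with record-level statistics.
#' @export
run_imminent_experiment <- function(fallers, cfg = pipeline_config(),
                                    seed = 1L, stratum = c("all", "short", "long")) {
  stratum <- match.arg(stratum)
  stopifnot(inherits(fallers, "nursing_corpus"))
  fallers <- subset_corpus(
    fallers, fallers$patients$patient_id[fallers$patients$label == "faller"],
    "faller data set")
  fallers <- prepare_corpus(fallers, cfg)
  fallers <- tag_imminent(fallers, cfg$imminent_window, cfg$include_fall_day)
  if (!any(fallers$records$imminent == "imminent"))
    stop("no imminent records in the window; nothing to detect")
  if (stratum != "all")
    fallers <- stratify_by_stay(fallers)[[stratum]]

  seeds <- derive_seeds(seed, 3L)
  halves <- split_patients(fallers, cfg$fraction, seed = seeds[1],
                           stratify = FALSE)
  fit <- fit_fall_risk(halves$part1, cfg, target = "imminent", seed = seeds[2],
                       allow_empty = TRUE)
  rec <- predict(fit, halves$part2, type = "record", seed = seeds[3])
  labels <- rec$imminent == "imminent"
  rep <- report_from_scores(rec$probability, labels)
  structure(c(rep, list(scores = rec, selected = fit$selected,
                        tally = fit$tally, fit = fit, seed = seed,
                        level = "record", target = "imminent",
                        stratum = stratum)),
            class = "fall_eval_report")
}

#' @export
print.fall_eval_report <- function(x, ...) {
  cat(sprintf("Evaluation report (%s-level, %s target)\n", x$level, x$target))
  cat(sprintf("  AUC: %.3f; threshold (closest to (0,1)): %.4f\n",
              x$auc, x$threshold))
  print(x$stats)
  invisible(x)
}

#' Repeat experiments and summarize reproducibility
#'
#' Runs [run_experiment()] once per seed and aggregates: mean and sample
#' standard deviation of AUC, sensitivity, specificity and odds ratio, and
#' the matrix of pairwise R-squared values of patient risk scores over the
#' patients shared by each pair of test sets.
#'
#' @param corpus the full case-control `nursing_corpus`.
#' @param cfg a [pipeline_config()].
#' @param seeds integer vector of seeds, one experiment each.
#' @return list with `reports`, `summary` (mean/sd data.frame) and
#'   `r2` (pairwise matrix).
#' @export
run_experiments <- function(corpus, cfg = pipeline_config(), seeds = 1:5) {
  reports <- lapply(seeds, function(s) run_experiment(corpus, cfg, seed = s))
  stat <- function(f) vapply(reports, f, numeric(1))
  vals <- data.frame(
    statistic = c("auc", "sensitivity", "specificity", "odds_ratio"),
    mean = c(mean(stat(function(r) r$auc)),
             mean(stat(function(r) r$stats$sensitivity)),
             mean(stat(function(r) r$stats$specificity)),
             mean(stat(function(r) r$stats$odds_ratio))),
    sd = c(stats::sd(stat(function(r) r$auc)),
           stats::sd(stat(function(r) r$stats$sensitivity)),
           stats::sd(stat(function(r) r$stats$specificity)),
           stats::sd(stat(function(r) r$stats$odds_ratio))))
  k <- length(reports)
  r2 <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i >= j) next
    a <- reports[[i]]$scores
    b <- reports[[j]]$scores
    common <- intersect(a$patient_id, b$patient_id)
    if (length(common) < 3L) next
    a <- a[a$patient_id %in% common, ]
    b <- b[b$patient_id %in% common, ]
    class(a) <- class(b) <- c("patient_risk_scores", "data.frame")
    r2[i, j] <- cross_run_r2(a, b)
  }
  list(reports = reports, summary = vals, r2 = r2)
}
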
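#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Brings the minority class up to the majority count by interpolating
#' between minority rows: each synthetic row lies uniformly on the segment
#' between a minority row and one of its `k_neighbors` nearest minority
#' neighbours (Euclidean distance in feature space). Original rows are
#' retained unchanged.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y binary labels (0/1, logical, or a 2-level factor/character).
#' @param k_neighbors neighbourhood size (default 5; must be smaller than
#'   the minority count).
#' @param seed integer seed.
#' @return list with balanced `X` and `y`; synthetic rows are appended after
#'   the originals.
#' @export
oversample_minority <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.vector(y)
  if (nrow(X) != length(y)) stop("X and y disagree in length")
  tab <- table(y)
  if (length(tab) < 2L) stop("both classes must be present for oversampling")
  if (length(tab) > 2L) stop("y must be binary")
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min == n_maj) return(list(X = X, y = y))
  if (n_min <= k_neighbors)
    stop("minority count (", n_min, ") must exceed k_neighbors (",
         k_neighbors, "); use a smaller k_neighbors")
  idx_min <- which(y == minority)
  M <- X[idx_min, , drop = FALSE]

  # k nearest minority neighbours via the squared-distance expansion
  sq <- rowSums(M^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(M)
  diag(d2) <- Inf
  nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k_neighbors)]))

  n_syn <- as.integer(n_maj - n_min)
  syn <- with_seed(seed, {
    base <- sample(rep_len(seq_len(nrow(M)), n_syn))
    nbr <- nn[cbind(base, sample.int(k_neighbors, n_syn, replace = TRUE))]
    gap <- stats::runif(n_syn)
    M[base, , drop = FALSE] + gap * (M[nbr, , drop = FALSE] - M[base, , drop = FALSE])
  })
  list(X = rbind(X, syn),
       y = c(y, rep(minority, n_syn)))
}

#' Fit a Bayesian logistic regression by Hamiltonian Monte Carlo
#'
#' Fits `P(y = 1 | x) = plogis(b0 + x b)` with independent Normal(0,
#' `prior_sd`^2) priors on the intercept and every coefficient. Sampling is
#' Hamiltonian Monte Carlo preconditioned with the posterior Hessian at the
#' MAP (found by L-BFGS), which makes short trajectories mix well even with
#' strongly correlated features. Point estimates are posterior means;
#' convergence is monitored with the split-chain potential scale reduction
#' factor (flagged when any parameter exceeds 1.05).
#'
#' @param X numeric feature matrix; column names become coefficient names.
#' @param y numeric/logical 0-1 labels (1 = case) with both classes present.
#' @param prior_sd prior standard deviation (default 1).
#' @param intercept include a fitted intercept (default `TRUE`).
#' @param chains number of chains (default 2).
#' @param warmup,iter warmup and retained iterations per chain (defaults
#'   300/500, so 1000 retained draws with two chains).
#' @param L_max leapfrog steps are drawn uniformly from 1..`L_max`.
#' @param seed integer seed.
#' @return an object of class `logistic_risk_model`: posterior draws,
#'   posterior means/sds, vocabulary (feature names), convergence
#'   diagnostics, and slots for the feature standardization used by the
#'   pipeline wrappers.
#' @export
fit_bayesian_logistic <- function(X, y, prior_sd = 1, intercept = TRUE,
                                  chains = 2L, warmup = 300L, iter = 500L,
                                  L_max = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) == 0L) stop("no data")
  if (!all(y %in% c(0, 1))) stop("y must be coded 0/1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!all(is.finite(X))) stop("X must be finite")
  if (prior_sd <= 0) stop("prior_sd must be positive")
  vocab <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  colnames(X) <- vocab

  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  p <- ncol(Xd)
  prec <- rep(1 / prior_sd^2, p)

  nlp <- function(b) {
    eta <- drop(Xd %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) + 0.5 * sum(prec * b^2)
  }
  grad <- function(b) {
    eta <- drop(Xd %*% b)
    drop(crossprod(Xd, stats::plogis(eta) - y)) + prec * b
  }
  opt <- stats::optim(rep(0, p), nlp, grad, method = "L-BFGS-B",
                      control = list(maxit = 200))
  bmap <- opt$par
  w <- stats::plogis(drop(Xd %*% bmap))
  H <- crossprod(Xd * sqrt(w * (1 - w))) + diag(prec, p)
  U <- chol(H)

  draws <- vector("list", chains)
  accept <- numeric(chains)
  sub_seeds <- derive_seeds(seed, chains)
  for (ch in seq_len(chains)) {
    # overdisperse starts for chains beyond the first
    start <- bmap
    if (ch > 1L) {
      z <- with_seed(sub_seeds[ch] + 1L, stats::rnorm(p))
      start <- bmap + backsolve(U, z)
    }
    run <- .hmc_logistic_cpp(Xd, y, prec, start, U, warmup, iter,
                             as.integer(L_max), 0.5, 0.8,
                             as.integer(sub_seeds[ch] %% .Machine$integer.max))
    colnames(run$samples) <- colnames(Xd)
    draws[[ch]] <- run$samples
    accept[ch] <- run$accept_rate
  }
  rhat <- split_rhat(draws)
  all_draws <- do.call(rbind, draws)
  post_mean <- colMeans(all_draws)
  post_sd <- apply(all_draws, 2L, stats::sd)
  converged <- max(rhat) < 1.05
  if (!converged)
    warning("MCMC convergence flag: max split R-hat = ",
            round(max(rhat), 3), " >= 1.05")

  structure(list(
    coefficients = post_mean[vocab],
    intercept = if (intercept) unname(post_mean["(Intercept)"]) else 0,
    posterior = all_draws,
    posterior_sd = post_sd,
    prior_sd = prior_sd,
    vocabulary = vocab,
    has_intercept = intercept,
    rhat = rhat,
    max_rhat = max(rhat),
    accept_rate = accept,
    converged = converged,
    center = NULL, scale = NULL,
    n_obs = nrow(X),
    seed = seed
  ), class = "logistic_risk_model")
}

#' @export
print.logistic_risk_model <- function(x, ...) {
  cat("Bayesian logistic risk model\n")
  cat(sprintf("  features: %d; draws: %d; prior sd: %g\n",
              length(x$vocabulary), nrow(x$posterior), x$prior_sd))
  cat(sprintf("  max split R-hat: %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.logistic_risk_model <- function(object, ...) {
  if (object$has_intercept)
    c("(Intercept)" = object$intercept, object$coefficients)
  else object$coefficients
}

#' @export
summary.logistic_risk_model <- function(object, level = 0.95, ...) {
  a <- (1 - level) / 2
  q <- apply(object$posterior, 2L, stats::quantile, probs = c(a, 1 - a))
  out <- data.frame(term = colnames(object$posterior),
                    estimate = colMeans(object$posterior),
                    sd = apply(object$posterior, 2L, stats::sd),
                    lower = q[1L, ], upper = q[2L, ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$lower > 0 | out$upper < 0
  class(out) <- c("summary.logistic_risk_model", "data.frame")
  out
}

#' Record-level risk probabilities
#'
#' Applies the logistic model to rows of a (trimmed) document-word matrix:
#' `p = plogis(b0 + d . b)` for each row d, after applying any feature
#' standardization stored in the model. Rows flagged degenerate (documents
#' with no in-vocabulary token) receive the neutral probability 0.5.
#'
#' @param model a `logistic_risk_model`.
#' @param dw_rows matrix whose columns match the model vocabulary (a
#'   wider `dw_matrix` is trimmed by name).
#' @return numeric vector of probabilities in (0, 1), named by row.
#' @export
predict_risk <- function(model, dw_rows) {
  stopifnot(inherits(model, "logistic_risk_model"))
  X <- as.matrix(dw_rows)
  if (!is.null(colnames(X))) {
    missing <- setdiff(model$vocabulary, colnames(X))
    if (length(missing))
      stop("feature columns missing: ", paste(utils::head(missing, 5), collapse = ", "))
    degen <- attr(dw_rows, "degenerate")
    X <- X[, model$vocabulary, drop = FALSE]
  } else {
    if (ncol(X) != length(model$vocabulary))
      stop("feature width ", ncol(X), " does not match model vocabulary (",
           length(model$vocabulary), ")")
    degen <- attr(dw_rows, "degenerate")
  }
  if (!is.null(model$center))
    X <- sweep(X, 2L, model$center, "-")
  if (!is.null(model$scale))
    X <- sweep(X, 2L, model$scale, "/")
  p <- stats::plogis(model$intercept + drop(X %*% model$coefficients))
  if (!is.null(degen)) p[degen] <- 0.5
  names(p) <- rownames(dw_rows)
  p
}

#' @export
predict.logistic_risk_model <- function(object, newdata, ...) {
  predict_risk(object, newdata)
}

#' Words with posterior weight significantly different from zero
#'
#' A word is significant when the equal-tailed `level` credible interval of
#' its coefficient's posterior excludes zero.
#'
#' @param model a `logistic_risk_model`.
#' @param level credible level (default 0.95).
#' @return character vector of significant words, in vocabulary order.
#' @export
significant_words <- function(model, level = 0.95) {
  stopifnot(inherits(model, "logistic_risk_model"))
  a <- (1 - level) / 2
  n <- nrow(model$posterior)
  if (n * a < 1)
    stop("too few posterior draws (", n, ") for level ", level)
  draws <- model$posterior[, model$vocabulary, drop = FALSE]
  lo <- apply(draws, 2L, stats::quantile, probs = a)
  hi <- apply(draws, 2L, stats::quantile, probs = 1 - a)
  model$vocabulary[lo > 0 | hi < 0]
}

# standardize columns; returns list(X, center, scale). Zero-variance columns
# keep scale 1 so they pass through (the prior regularizes their weight).
standardize_columns <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
    scale[scale < .Machine$double.eps] <- 1
  }
  list(X = sweep(sweep(X, 2L, center, "-"), 2L, scale, "/"),
       center = center, scale = scale)
}

# labels for a record-level classification target
record_labels <- function(corpus, target = c("faller", "imminent")) {
  target <- match.arg(target)
  if (target == "faller") {
    lab <- corpus$patients$label[match(corpus$records$patient_id,
                                       corpus$patients$patient_id)]
    as.numeric(lab == "faller")
  } else {
    imm <- corpus$records$imminent
    if (any(imm == "untagged"))
      stop("imminent target requires a tagged faller corpus; run tag_imminent() first")
    as.numeric(imm == "imminent")
  }
}

# standardize -> SMOTE -> fit; the shared inner step of the ensemble and the
# final model
fit_on_dw <- function(dw, y, cfg, seed) {
  std <- standardize_columns(unclass(dw))
  bal <- oversample_minority(std$X, y, k_neighbors = cfg$smote_k, seed = seed)
  model <- fit_bayesian_logistic(bal$X, as.numeric(bal$y), prior_sd = cfg$prior_sd,
                                 chains = cfg$chains, warmup = cfg$warmup,
                                 iter = cfg$iter, L_max = cfg$L_max,
                                 seed = seed)
  model$center <- std$center
  model$scale <- std$scale
  model
}

#' Run the bisection ensemble and tally significant words
#'
#' Randomly bisects the learning set at the patient level `bisections`
#' times (default 3), yielding `2 * bisections` sub-corpora. On each
#' sub-corpus the record-level document-word features are standardized,
#' SMOTE-balanced and fitted with [fit_bayesian_logistic()]; each fit's
#' [significant_words()] votes for its words. The tally counts, per word,
#' in how many of the six primary models the word was significant.
#'
#' Embeddings are trained once on the full learning corpus and shared by
#' all six primary models, isolating the vocabulary-selection signal from
#' embedding noise.
#'
#' @param corpus the learning `nursing_corpus`.
#' @param cfg a [pipeline_config()].
#' @param target `"faller"` (fall prediction) or `"imminent"` (pre-fall
#'   precursor detection at the record level).
#' @param seed integer seed driving the bisections and fits.
#' @param dw optionally, a precomputed `dw_matrix` for the corpus records
#'   (rows in corpus record order); computed from scratch when `NULL`.
#' @return a `significance_tally`: named integer vector of votes over the
#'   vocabulary with attributes `n_models` and `level`.
#' @export
run_bisection_ensemble <- function(corpus, cfg = pipeline_config(),
                                   target = "faller", seed = 1L, dw = NULL) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (is.null(dw)) {
    vocab <- build_vocabulary(corpus, cfg$top_k, cfg$min_count)
    emb <- train_embeddings(corpus, vocab, as_embedding_config(cfg, seed))
    dw <- compute_dw(emb$D, emb$W)
  }
  y_all <- record_labels(corpus, target)
  if (length(unique(y_all)) < 2L) stop("learning corpus has a single class")
  rid <- record_ids(corpus$records)
  stopifnot(identical(rownames(unclass(dw)), rid))

  words <- colnames(dw)
  counts <- stats::setNames(integer(length(words)), words)
  seeds <- derive_seeds(seed, cfg$bisections * 3L)
  model_i <- 0L
  for (b in seq_len(cfg$bisections)) {
    halves <- split_patients(corpus, 0.5, seed = seeds[b], stratify = cfg$stratify)
    for (half in halves) {
      model_i <- model_i + 1L
      idx <- which(corpus$records$patient_id %in% half$patients$patient_id)
      y <- y_all[idx]
      if (length(unique(y)) < 2L)
        stop("bisection ", b, " produced a single-class half; re-run with a different seed")
      model <- fit_on_dw(dw[idx, , drop = FALSE], y, cfg,
                         seed = seeds[cfg$bisections + model_i])
      sig <- significant_words(model, cfg$level)
      counts[sig] <- counts[sig] + 1L
    }
  }
  structure(counts, n_models = model_i, level = cfg$level,
            class = "significance_tally")
}

#' @export
print.significance_tally <- function(x, ...) {
  nm <- attr(x, "n_models")
  cat(sprintf("Significance tally over %d primary models (%d words)\n",
              nm, length(x)))
  print(table(factor(as.integer(x), levels = 0:nm)))
  invisible(x)
}

#' Select the stable vocabulary from an ensemble tally
#'
#' @param tally a `significance_tally`.
#' @param min_models minimum number of primary models in which a word must
#'   be significant (default 4 of 6).
#' @return character vector of selected words in vocabulary order; empty
#'   (with a warning) when `min_models` exceeds the number of models.
#' @export
select_vocabulary <- function(tally, min_models = 4L) {
  stopifnot(inherits(tally, "significance_tally"))
  if (min_models > attr(tally, "n_models")) {
    warning("min_models (", min_models, ") exceeds the number of primary models (",
            attr(tally, "n_models"), "); selecting nothing")
    return(character())
  }
  names(tally)[tally >= min_models]
}

#' Fit the final trimmed risk model
#'
#' Restricts the learning-set document-word matrix to the selected
#' vocabulary and refits the Bayesian logistic regression on the full
#' learning set (standardize, SMOTE, HMC).
#'
#' @param corpus the learning `nursing_corpus`.
#' @param selected non-empty character vector of selected words.
#' @param cfg a [pipeline_config()].
#' @param target as in [run_bisection_ensemble()].
#' @param seed integer seed.
#' @param dw optional precomputed `dw_matrix` over the full vocabulary.
#' @return a `logistic_risk_model` whose vocabulary is `selected`.
#' @export
build_final_model <- function(corpus, selected, cfg = pipeline_config(),
                              target = "faller", seed = 1L, dw = NULL) {
  if (!length(selected)) stop("selected vocabulary is empty")
  if (is.null(dw)) {
    vocab <- build_vocabulary(corpus, cfg$top_k, cfg$min_count)
    emb <- train_embeddings(corpus, vocab, as_embedding_config(cfg, seed))
    dw <- compute_dw(emb$D, emb$W)
  }
  y <- record_labels(corpus, target)
  fit_on_dw(trim_columns(dw, selected), y, cfg, seed = seed)
}
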
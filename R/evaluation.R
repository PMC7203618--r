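#' Aggregate record probabilities into patient risk scores
#'
#' A patient's risk score is the arithmetic mean of the risk probabilities
#' of all their scored nursing records.
#'
#' @param probabilities either a data.frame with columns `patient_id` and
#'   `probability` (as returned by `predict()` on a fitted model), or a
#'   numeric vector named by record id (`patient::date`).
#' @param corpus the `nursing_corpus` the records belong to; patients with
#'   no scored records are dropped with a warning.
#' @return a `patient_risk_scores` data.frame with columns `patient_id`,
#'   `score`, `n_records`, `label`.
#' @export
patient_scores <- function(probabilities, corpus) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (is.data.frame(probabilities)) {
    pid <- probabilities$patient_id
    p <- probabilities$probability
  } else {
    p <- as.numeric(probabilities)
    pid <- sub("::.*$", "", names(probabilities))
  }
  if (!length(p)) stop("no probabilities supplied")
  unknown <- setdiff(unique(pid), corpus$patients$patient_id)
  if (length(unknown))
    stop("scored records reference unknown patients: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  agg <- tapply(p, factor(pid, levels = corpus$patients$patient_id), mean)
  n <- tapply(p, factor(pid, levels = corpus$patients$patient_id), length)
  missing <- is.na(agg)
  if (any(missing))
    warning(sum(missing), " patient(s) with no scored records excluded")
  out <- data.frame(patient_id = corpus$patients$patient_id[!missing],
                    score = as.numeric(agg[!missing]),
                    n_records = as.integer(n[!missing]),
                    label = corpus$patients$label[!missing],
                    stringsAsFactors = FALSE)
  class(out) <- c("patient_risk_scores", "data.frame")
  out
}

scores_and_labels <- function(scores, labels = NULL) {
  if (inherits(scores, "patient_risk_scores")) {
    list(values = scores$score, positive = scores$label == "faller")
  } else {
    if (is.null(labels)) stop("labels required for a plain score vector")
    if (is.character(labels)) labels <- labels %in% c("faller", "imminent", "1")
    list(values = as.numeric(scores), positive = as.logical(labels))
  }
}

#' ROC curve and AUC
#'
#' Scans all distinct score values as cutoffs (predicted positive iff
#' score >= cutoff), plus the two endpoints; tied scores move the curve in
#' one simultaneous step. The AUC is the trapezoidal area, identical to the
#' Mann-Whitney pair statistic with ties counted 1/2.
#'
#' @param scores a `patient_risk_scores` data.frame (positive class =
#'   faller), or a numeric vector.
#' @param labels when `scores` is a plain vector: logical/0-1 positives.
#' @return a `roc_curve`: list with `points` (data.frame `cutoff`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels = NULL) {
  sl <- scores_and_labels(scores, labels)
  pos <- sl$positive
  v <- sl$values
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present for a ROC curve")
  ord <- order(v, decreasing = TRUE)
  v <- v[ord]; pos <- pos[ord]
  grp <- cumsum(!duplicated(v))           # tie groups in descending order
  tp <- tapply(pos, grp, sum)
  fp <- tapply(!pos, grp, sum)
  tpr <- cumsum(tp) / n1
  fpr <- cumsum(fp) / n0
  cutoffs <- v[!duplicated(v)]
  points <- data.frame(cutoff = c(Inf, cutoffs),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives / %d negatives, AUC = %.3f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Operating point closest to the perfect classifier
#'
#' Returns the cutoff whose ROC point minimizes the Euclidean distance to
#' the corner (0, 1); ties are broken toward the lower cutoff.
#'
#' @param curve a `roc_curve`.
#' @return the selected cutoff.
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  pts <- curve$points
  d2 <- pts$fpr^2 + (1 - pts$tpr)^2
  best <- which(d2 <= min(d2) + 1e-12)
  min(pts$cutoff[best])
}

#' Confusion matrix at a threshold
#'
#' Predicted positive ("risk") iff score >= threshold.
#'
#' @param scores a `patient_risk_scores` data.frame or numeric vector.
#' @param threshold cutoff in \[0, 1\].
#' @param labels labels for a plain score vector.
#' @return a `confusion_matrix`: list with integer counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_at <- function(scores, threshold, labels = NULL) {
  sl <- scores_and_labels(scores, labels)
  pred <- sl$values >= threshold
  confusion_matrix(tp = sum(pred & sl$positive),
                   fp = sum(pred & !sl$positive),
                   fn = sum(!pred & sl$positive),
                   tn = sum(!pred & !sl$positive))
}

#' Construct a confusion matrix from counts
#'
#' Rows are predicted risk/no-risk, columns true case/control status.
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return a `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(prediction = c("risk", "no risk"),
                              truth = c("case", "control")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and odds ratio with confidence intervals
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` (Wilson
#' score intervals by default, Wald optionally) and the odds ratio
#' `(tp*tn)/(fp*fn)` with the Woolf logit interval
#' `exp(log(OR) +- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn))`. A zero cell
#' triggers the Haldane-Anscombe +0.5 correction for the odds ratio (and is
#' flagged in the result).
#'
#' @param cm a `confusion_matrix`.
#' @param ci_method `"wilson"` (default) or `"wald"` for the proportions.
#' @param level confidence level (default 0.95).
#' @return a `confusion_stats` list with the three estimates and their
#'   confidence intervals.
#' @export
confusion_stats <- function(cm, ci_method = c("wilson", "wald"), level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  z <- stats::qnorm(1 - (1 - level) / 2)

  prop_ci <- function(x, n) {
    if (n == 0L) return(c(NA_real_, NA_real_))
    if (ci_method == "wilson") {
      tst <- suppressWarnings(stats::prop.test(x, n, conf.level = level,
                                               correct = FALSE))
      as.numeric(tst$conf.int)
    } else {
      p <- x / n
      se <- sqrt(p * (1 - p) / n)
      c(max(0, p - z * se), min(1, p + z * se))
    }
  }

  sens_n <- cm$tp + cm$fn
  spec_n <- cm$tn + cm$fp
  if (sens_n == 0L || spec_n == 0L)
    stop("both outcome columns must contain observations")
  sens <- cm$tp / sens_n
  spec <- cm$tn / spec_n

  cells <- c(cm$tp, cm$fp, cm$fn, cm$tn)
  haldane <- any(cells == 0L)
  cc <- if (haldane) cells + 0.5 else cells
  or <- (cc[1] * cc[4]) / (cc[2] * cc[3])
  se_log <- sqrt(sum(1 / cc))
  or_ci <- exp(log(or) + c(-1, 1) * z * se_log)

  structure(list(
    sensitivity = sens, sensitivity_ci = prop_ci(cm$tp, sens_n),
    specificity = spec, specificity_ci = prop_ci(cm$tn, spec_n),
    odds_ratio = or, odds_ratio_ci = or_ci,
    haldane_corrected = haldane,
    ci_method = ci_method, level = level, confusion = cm
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("sensitivity: %.3f (%.3f-%.3f)\n",
              x$sensitivity, x$sensitivity_ci[1], x$sensitivity_ci[2]))
  cat(sprintf("specificity: %.3f (%.3f-%.3f)\n",
              x$specificity, x$specificity_ci[1], x$specificity_ci[2]))
  cat(sprintf("odds ratio:  %.2f (%.2f-%.2f)%s\n",
              x$odds_ratio, x$odds_ratio_ci[1], x$odds_ratio_ci[2],
              if (x$haldane_corrected) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Cross-experiment reproducibility (R squared)
#'
#' Coefficient of determination of the ordinary least-squares regression of
#' one experiment's patient risk scores on another's, over the same patient
#' set.
#'
#' @param scores_a,scores_b `patient_risk_scores` for the same patients.
#' @return R squared in \[0, 1\].
#' @export
cross_run_r2 <- function(scores_a, scores_b) {
  stopifnot(inherits(scores_a, "patient_risk_scores"),
            inherits(scores_b, "patient_risk_scores"))
  if (!setequal(scores_a$patient_id, scores_b$patient_id))
    stop("patient sets differ; restrict both score tables to their common patients")
  b <- scores_b$score[match(scores_a$patient_id, scores_b$patient_id)]
  a <- scores_a$score
  summary(stats::lm(b ~ a))$r.squared
}
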
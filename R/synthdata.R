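#' Configuration for the synthetic corpus generator
#'
#' Defines a seeded case-control corpus with known ground truth. Background
#' tokens follow a Zipf law (exponent `zipf_exponent`) over `vocab_size`
#' types; planted risk, protective and precursor tokens are added on top at
#' the frequency of Zipf rank `planted_rank`, so they sit comfortably inside
#' the top-1000 vocabulary cut the embedding stage applies. Risk tokens are
#' `exp(effect_log_odds)` times more frequent in faller records than in
#' nonfaller records (protective tokens the reciprocal); precursor tokens are
#' boosted by `precursor_boost` inside the imminent pre-fall window.
#'
#' Record-count structure mirrors the case-control corpora this emulates:
#' fallers accumulate more records than nonfallers (negative-binomial
#' record counts with class-specific means), and a small fraction of records
#' is emitted very short to exercise the character-count exclusion filter.
#'
#' @param n_fallers,n_nonfallers patient counts per class.
#' @param vocab_size number of background token types.
#' @param n_risk_tokens,n_protective_tokens,n_precursor_tokens planted counts.
#' @param effect_log_odds log frequency ratio between classes for planted
#'   risk/protective tokens.
#' @param records_mean_faller,records_mean_nonfaller mean records per patient.
#' @param records_dispersion negative-binomial size for record counts.
#' @param tokens_per_record,tokens_dispersion mean/size of tokens per record.
#' @param short_record_rate fraction of records emitted with 1-8 tokens
#'   (these fall below the 50-character exclusion threshold).
#' @param imminent_window days before a fall within which precursor tokens
#'   are boosted.
#' @param precursor_boost multiplicative in-window frequency factor.
#' @param mean_extra_falls expected number of falls beyond the first per
#'   faller (Poisson).
#' @param zipf_exponent exponent of the background frequency law.
#' @param planted_rank background rank whose frequency the planted tokens
#'   share.
#' @param seed integer seed (set by the caller).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_fallers = 150L, n_nonfallers = 200L,
                             vocab_size = 2000L,
                             n_risk_tokens = 20L, n_protective_tokens = 10L,
                             n_precursor_tokens = 15L,
                             effect_log_odds = 1.0,
                             records_mean_faller = 50, records_mean_nonfaller = 30,
                             records_dispersion = 3,
                             tokens_per_record = 80, tokens_dispersion = 20,
                             short_record_rate = 0.05,
                             imminent_window = 7L, precursor_boost = 3,
                             mean_extra_falls = 0.3,
                             zipf_exponent = 1.0, planted_rank = 60L,
                             seed = NULL) {
  cfg <- list(n_fallers = as.integer(n_fallers),
              n_nonfallers = as.integer(n_nonfallers),
              vocab_size = as.integer(vocab_size),
              n_risk_tokens = as.integer(n_risk_tokens),
              n_protective_tokens = as.integer(n_protective_tokens),
              n_precursor_tokens = as.integer(n_precursor_tokens),
              effect_log_odds = effect_log_odds,
              records_mean_faller = records_mean_faller,
              records_mean_nonfaller = records_mean_nonfaller,
              records_dispersion = records_dispersion,
              tokens_per_record = tokens_per_record,
              tokens_dispersion = tokens_dispersion,
              short_record_rate = short_record_rate,
              imminent_window = as.integer(imminent_window),
              precursor_boost = precursor_boost,
              mean_extra_falls = mean_extra_falls,
              zipf_exponent = zipf_exponent,
              planted_rank = as.integer(planted_rank),
              seed = seed)
  if (cfg$n_fallers < 1L || cfg$n_nonfallers < 0L)
    stop("need at least one faller and a non-negative nonfaller count")
  if (cfg$vocab_size < 10L) stop("vocab_size too small")
  if (cfg$precursor_boost <= 0) stop("precursor_boost must be positive")
  structure(cfg, class = "generator_config")
}

#' The frozen standard benchmark configuration
#'
#' The fixed generator settings used by the package's synthetic benchmark:
#' 150 fallers and 200 nonfallers, 2000 background tokens, 20 risk and 10
#' protective tokens at a log frequency ratio of 1.0, negative-binomial
#' record counts with means 50 (fallers) and 30 (nonfallers), 80 tokens per
#' record, and 15 precursor tokens boosted 3-fold inside a 7-day pre-fall
#' window. The seed is left to the caller.
#'
#' @param seed integer seed passed through to [generator_config()].
#' @return a `generator_config`.
#' @export
standard_benchmark <- function(seed = NULL) {
  generator_config(seed = seed)
}

planted_tokens <- function(cfg) {
  list(risk = if (cfg$n_risk_tokens) sprintf("risk%02d", seq_len(cfg$n_risk_tokens)) else character(),
       protective = if (cfg$n_protective_tokens) sprintf("prot%02d", seq_len(cfg$n_protective_tokens)) else character(),
       precursor = if (cfg$n_precursor_tokens) sprintf("prec%02d", seq_len(cfg$n_precursor_tokens)) else character())
}

# Class-conditional unigram weights (unnormalized). Returns a named list of
# weight vectors for: nonfaller, faller out-of-window, faller in-window.
class_distributions <- function(cfg) {
  pl <- planted_tokens(cfg)
  bg_words <- sprintf("w%04d", seq_len(cfg$vocab_size))
  bg_w <- 1 / seq_len(cfg$vocab_size)^cfg$zipf_exponent
  base <- 1 / cfg$planted_rank^cfg$zipf_exponent
  words <- c(bg_words, pl$risk, pl$protective, pl$precursor)
  w_non <- c(bg_w, rep(base, length(pl$risk)), rep(base, length(pl$protective)),
             rep(base, length(pl$precursor)))
  w_fal <- c(bg_w, rep(base * exp(cfg$effect_log_odds), length(pl$risk)),
             rep(base * exp(-cfg$effect_log_odds), length(pl$protective)),
             rep(base, length(pl$precursor)))
  w_imm <- w_fal
  if (length(pl$precursor)) {
    idx <- cfg$vocab_size + length(pl$risk) + length(pl$protective) +
      seq_along(pl$precursor)
    w_imm[idx] <- w_imm[idx] * cfg$precursor_boost
  }
  list(words = words,
       nonfaller = w_non / sum(w_non),
       faller = w_fal / sum(w_fal),
       faller_imminent = w_imm / sum(w_imm))
}

#' Generate a synthetic case-control corpus
#'
#' Emits a pre-tokenized corpus with the structure described in
#' [generator_config()] together with its ground truth. Fallers receive one
#' or more fall dates placed uniformly within their record span; records in
#' the 1-to-`imminent_window`-day window before any fall draw precursor
#' tokens at `precursor_boost` times their background rate. Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a `generator_config` with a non-`NULL` seed.
#' @return list with elements `corpus` (a `nursing_corpus`) and `truth`
#'   (planted token lists, class-conditional distributions, per-patient
#'   classes and fall dates).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(cfg$seed)) stop("generator_config seed must be set")
  n_pat <- cfg$n_fallers + cfg$n_nonfallers
  if (n_pat < 2L) stop("degenerate config: need at least 2 patients")
  dists <- class_distributions(cfg)
  pl <- planted_tokens(cfg)
  origin <- as.Date("2024-01-01")

  with_seed(cfg$seed, {
    labels <- c(rep("faller", cfg$n_fallers), rep("nonfaller", cfg$n_nonfallers))
    pids <- sprintf("P%04d", seq_len(n_pat))
    n_rec <- pmax(1L, stats::rnbinom(
      n_pat, size = cfg$records_dispersion,
      mu = ifelse(labels == "faller", cfg$records_mean_faller,
                  cfg$records_mean_nonfaller)))
    starts <- origin + sample.int(365L, n_pat, replace = TRUE) - 1L

    fall_dates <- vector("list", n_pat)
    for (i in seq_len(n_pat)) {
      if (labels[i] != "faller") {
        fall_dates[[i]] <- as.Date(character())
        next
      }
      span <- seq(starts[i], by = "day", length.out = n_rec[i])
      n_falls <- min(1L + stats::rpois(1L, cfg$mean_extra_falls), length(span))
      fall_dates[[i]] <- sort(sample(span, n_falls))
    }

    rec_pid <- rep(pids, n_rec)
    rec_lab <- rep(labels, n_rec)
    rec_date <- origin + unlist(lapply(seq_len(n_pat), function(i) {
      as.integer(starts[i] - origin) + seq_len(n_rec[i]) - 1L
    }), use.names = FALSE)
    m <- length(rec_pid)

    # imminent window membership (precursor boosting only; tagging is left
    # to tag_imminent so the generated corpus arrives untagged)
    fall_by_pid <- stats::setNames(fall_dates, pids)
    in_window <- vapply(seq_len(m), function(j) {
      if (rec_lab[j] != "faller") return(FALSE)
      falls <- fall_by_pid[[rec_pid[j]]]
      any(rec_date[j] >= falls - cfg$imminent_window & rec_date[j] <= falls - 1L)
    }, logical(1))

    short <- stats::runif(m) < cfg$short_record_rate
    n_tok <- ifelse(short,
                    sample(1:8, m, replace = TRUE),
                    pmax(1L, stats::rnbinom(m, size = cfg$tokens_dispersion,
                                            mu = cfg$tokens_per_record)))
    tokens <- vector("list", m)
    for (j in seq_len(m)) {
      p <- if (rec_lab[j] != "faller") dists$nonfaller
           else if (in_window[j]) dists$faller_imminent
           else dists$faller
      tokens[[j]] <- sample(dists$words, n_tok[j], replace = TRUE, prob = p)
    }

    patients <- data.frame(patient_id = pids, label = labels,
                           stringsAsFactors = FALSE)
    patients$fall_dates <- fall_dates
    patients$age <- round(stats::rnorm(n_pat,
                                       mean = ifelse(labels == "faller", 73, 65),
                                       sd = 15))
    patients$sex <- sample(c("F", "M"), n_pat, replace = TRUE)
    records <- data.frame(patient_id = rec_pid, date = rec_date,
                          stringsAsFactors = FALSE)
    records$tokens <- tokens
    corpus <- nursing_corpus(patients, records,
                             provenance = sprintf("synthetic corpus (seed %d)", cfg$seed))
    truth <- list(risk_tokens = pl$risk, protective_tokens = pl$protective,
                  precursor_tokens = pl$precursor,
                  distributions = dists,
                  patient_class = stats::setNames(labels, pids),
                  fall_dates = fall_by_pid,
                  config = cfg)
    list(corpus = corpus, truth = truth)
  })
}

#' Generate a signal-free control corpus
#'
#' Same structural skeleton as [generate_corpus()] but with every planted
#' effect removed: no risk/protective/precursor tokens and no in-window
#' boost, so the class labels carry no textual signal. Used for null
#' calibration of the pipeline.
#'
#' @param cfg a `generator_config`; its effect parameters are zeroed.
#' @return as [generate_corpus()]; the ground-truth planted lists are empty.
#' @export
null_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  cfg$effect_log_odds <- 0
  cfg$precursor_boost <- 1
  cfg$n_risk_tokens <- 0L
  cfg$n_protective_tokens <- 0L
  cfg$n_precursor_tokens <- 0L
  generate_corpus(cfg)
}
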
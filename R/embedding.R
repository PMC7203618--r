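#' Embedding hyperparameters
#'
#' @param dim embedding dimension k (default 300).
#' @param negatives number of negative samples per observed pair (default 5).
#' @param top_k vocabulary cap: only the `top_k` most frequent tokens are
#'   embedded (default 1000).
#' @param window skip-gram context window; the effective window per position
#'   is drawn uniformly from 1..`window` as in word2vec (default 5).
#' @param epochs training passes over the corpus (default 20).
#' @param min_count minimum corpus frequency for a token to enter the
#'   vocabulary (default 1, within the `top_k` cap).
#' @param alpha,min_alpha linear learning-rate schedule endpoints.
#' @param smoothing additive smoothing constant of the document profile
#'   solution (default 0.5): the finite stand-in for the unbounded
#'   log-profile optimum at words absent from a document, playing the role
#'   early stopping plays in stochastic PV-DBOW inference.
#' @param seed integer seed; training is single-threaded and bit-reproducible.
#' @return list of class `embedding_config`.
#' @export
embedding_config <- function(dim = 300L, negatives = 5L, top_k = 1000L,
                             window = 5L, epochs = 20L, min_count = 1L,
                             alpha = 0.025, min_alpha = 1e-4,
                             smoothing = 0.5, seed = 1L) {
  stopifnot(dim >= 1, negatives >= 1, top_k >= 1, window >= 0, epochs >= 1,
            smoothing > 0)
  structure(list(dim = as.integer(dim), negatives = as.integer(negatives),
                 top_k = as.integer(top_k), window = as.integer(window),
                 epochs = as.integer(epochs), min_count = as.integer(min_count),
                 alpha = alpha, min_alpha = min_alpha,
                 smoothing = smoothing,
                 seed = as.integer(seed)),
            class = "embedding_config")
}

#' Build the embedding vocabulary
#'
#' Returns the `top_k` most frequent tokens over all records, ordered by
#' descending total corpus frequency with ties broken lexicographically.
#'
#' @param corpus a tokenized `nursing_corpus`.
#' @param top_k vocabulary cap (default 1000).
#' @param min_count minimum total frequency (default 1).
#' @return a `risk_vocabulary` data.frame with columns `word`, `frequency`.
#' @export
build_vocabulary <- function(corpus, top_k = 1000L, min_count = 1L) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (nrow(corpus$records) == 0L) stop("cannot build a vocabulary from an empty corpus")
  toks <- unlist(corpus$records$tokens, use.names = FALSE)
  if (!length(toks)) stop("corpus is not tokenized")
  counts <- table(toks)
  words <- names(counts)
  freq <- as.integer(counts)
  keep <- freq >= min_count
  words <- words[keep]; freq <- freq[keep]
  ord <- order(-freq, words, method = "radix")
  n <- min(length(words), as.integer(top_k))
  out <- data.frame(word = words[ord][seq_len(n)],
                    frequency = freq[ord][seq_len(n)],
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_vocabulary", "data.frame")
  out
}

vocab_words <- function(vocab) {
  if (inherits(vocab, "risk_vocabulary") || is.data.frame(vocab)) vocab$word
  else as.character(vocab)
}

# map record token lists to 0-based vocabulary ids, dropping out-of-vocab
docs_as_ids <- function(corpus, vocab) {
  words <- vocab_words(vocab)
  lapply(corpus$records$tokens, function(tk) {
    ids <- match(tk, words)
    as.integer(ids[!is.na(ids)] - 1L)
  })
}

noise_distribution <- function(vocab) {
  # unigram^(3/4), the standard negative-sampling noise distribution
  f <- vocab$frequency^0.75
  f / sum(f)
}

#' Train word and document embeddings jointly
#'
#' Trains skip-gram negative-sampling word vectors and PV-DBOW document
#' vectors in one pass, sharing the output (context) layer. The shared
#' output layer places word and document vectors in a common space, which is
#' what makes the document-word product matrix of [compute_dw()] an
#' interpretable affinity between each record and each vocabulary word.
#'
#' @param corpus a tokenized `nursing_corpus`.
#' @param vocab a `risk_vocabulary` from [build_vocabulary()].
#' @param cfg an `embedding_config`.
#' @return list of class `nursing_embeddings` with elements `W` (word
#'   matrix, n x k, rownames = words, with the output layer and config
#'   attached as attributes), `D` (document matrix, m x k, rownames =
#'   record ids) and `degenerate` (records with no in-vocabulary token).
#' @export
train_embeddings <- function(corpus, vocab, cfg = embedding_config()) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (nrow(vocab) == 0L) stop("vocabulary is empty")
  docs <- docs_as_ids(corpus, vocab)
  degenerate <- lengths(docs) == 0L
  fit <- .train_embeddings_cpp(docs, noise_distribution(vocab), nrow(vocab),
                               cfg$dim, cfg$window, cfg$negatives, cfg$epochs,
                               cfg$alpha, cfg$min_alpha, cfg$seed)
  # The exported word matrix is the shared context layer: both the skip-gram
  # and the PV-DBOW objectives train against it, so document vectors and
  # word vectors live in one space and D %*% t(W) is a document-word
  # affinity. The skip-gram input vectors are kept as an attribute for
  # word-word similarity queries.
  W <- fit$Wout
  rownames(W) <- vocab$word
  attr(W, "input") <- fit$W
  attr(W, "vocabulary") <- vocab
  attr(W, "config") <- cfg
  class(W) <- c("word_matrix", class(W))
  # document vectors solve the PV-DBOW objective exactly given the frozen
  # context layer; the same deterministic solution is used at inference time
  D <- solve_doc_vectors(docs, W, vocab, cfg)
  rownames(D) <- record_ids(corpus$records)
  D[degenerate, ] <- 0
  attr(D, "degenerate") <- degenerate
  structure(list(W = W, D = D, degenerate = degenerate, config = cfg),
            class = "nursing_embeddings")
}

#' Train word embeddings (skip-gram with negative sampling)
#'
#' Convenience wrapper around [train_embeddings()] returning only the word
#' matrix W (n x k, rows aligned to the vocabulary order).
#'
#' @inheritParams train_embeddings
#' @return a `word_matrix`.
#' @export
train_word_embeddings <- function(corpus, vocab, cfg = embedding_config()) {
  train_embeddings(corpus, vocab, cfg)$W
}

#' Train document embeddings (PV-DBOW)
#'
#' Convenience wrapper around [train_embeddings()] returning only the
#' document matrix D (m x k, rows aligned to record ids).
#'
#' @inheritParams train_embeddings
#' @return a numeric matrix with a `degenerate` attribute flagging records
#'   without in-vocabulary tokens.
#' @export
train_doc_embeddings <- function(corpus, vocab, cfg = embedding_config()) {
  train_embeddings(corpus, vocab, cfg)$D
}

# Closed-form PV-DBOW document vectors given a frozen context layer.
#
# For one document with word counts c and length n_d, the PV-DBOW
# negative-sampling objective decomposes over vocabulary words once the
# document vector is expressed through its affinity profile t = U d:
#   f(t) = sum_w [ c_w softplus(-t_w) + neg * n_d * q_w softplus(t_w) ]
# whose per-word optimum is t_w* = log(c_w / (neg * n_d * q_w)). The
# document vector is the minimum-norm vector realizing the smoothed optimal
# profile, d = U^+ t*, so that D W^T reproduces the profiles exactly when
# the context layer has full row rank (dim >= vocabulary size). Additive
# smoothing keeps the profile finite at absent words, standing in for the
# early stopping of stochastic inference.
solve_doc_vectors <- function(docs, W, vocab, cfg) {
  U <- unclass(W)
  attributes(U) <- list(dim = dim(W))
  q <- noise_distribution(vocab)
  n <- nrow(U)
  m <- length(docs)
  counts <- matrix(0, m, n)
  for (j in seq_len(m)) {
    ids <- docs[[j]] + 1L
    if (length(ids)) {
      tb <- tabulate(ids, nbins = n)
      counts[j, ] <- tb
    }
  }
  n_d <- vapply(docs, length, integer(1))
  gamma <- cfg$smoothing
  noise_mass <- outer(cfg$negatives * n_d, q)
  T_prof <- log((counts + gamma) / (noise_mass + gamma))
  T_prof[n_d == 0L, ] <- 0
  # minimum-norm solve: d = U' (U U')^{-1} t  (least squares when rank < n)
  G <- tcrossprod(U)
  B <- try(chol2inv(chol(G + diag(1e-8 * mean(diag(G)), n))) , silent = TRUE)
  if (inherits(B, "try-error")) B <- gram_pseudo_inverse(G)
  T_prof %*% (B %*% U)
}

# pseudo-inverse fallback for a rank-deficient gram matrix
gram_pseudo_inverse <- function(G, tol = 1e-10) {
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Infer document vectors for unseen records
#'
#' Embeds new documents by solving the PV-DBOW objective for each document
#' vector with the trained context layer and noise distribution frozen, so
#' no information flows from the new documents back into the model. This is
#' the same deterministic solution used for the training documents: a
#' training document re-inferred through this function reproduces its
#' training vector exactly. Documents with no in-vocabulary token are
#' flagged degenerate and embedded at the origin (their risk probability is
#' later fixed at 0.5).
#'
#' @param corpus a tokenized `nursing_corpus` of unseen records.
#' @param vocab the learning-set vocabulary.
#' @param W the trained `word_matrix` (the frozen shared context layer).
#' @param cfg an `embedding_config`; `negatives` and `smoothing` are used.
#'   The procedure is deterministic (no sampling).
#' @return m x k matrix with a `degenerate` logical attribute.
#' @export
infer_doc_vectors <- function(corpus, vocab, W, cfg = embedding_config()) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (!inherits(W, "word_matrix"))
    stop("W must be a trained word_matrix from train_embeddings()")
  docs <- docs_as_ids(corpus, vocab)
  degenerate <- lengths(docs) == 0L
  D <- solve_doc_vectors(docs, W, vocab, cfg)
  rownames(D) <- record_ids(corpus$records)
  D[degenerate, ] <- 0
  attr(D, "degenerate") <- degenerate
  D
}

#' Compute the document-word matrix
#'
#' Multiplies the document matrix by the transposed word matrix:
#' `DW = D %*% t(W)`, an m x n matrix whose entry (j, i) is the inner
#' product of document j's vector with word i's vector. Linearity of the
#' product means any linear relation among word vectors (for instance the
#' analogy relation w1 - w2 = w3 - w4) is inherited column-wise by DW.
#'
#' @param D m x k document matrix.
#' @param W n x k word matrix.
#' @return a `dw_matrix`: m x n matrix, columns named by vocabulary word,
#'   carrying the `degenerate` flag of `D`.
#' @export
compute_dw <- function(D, W) {
  if (ncol(D) != ncol(W))
    stop("dimension mismatch: D has k = ", ncol(D), ", W has k = ", ncol(W))
  DW <- unclass(D) %*% t(unclass(W))
  colnames(DW) <- rownames(W)
  attr(DW, "degenerate") <- attr(D, "degenerate") %||% rep(FALSE, nrow(DW))
  class(DW) <- c("dw_matrix", class(DW))
  DW
}

#' Restrict a document-word matrix to selected words
#'
#' @param dw a `dw_matrix`.
#' @param keep character vector of vocabulary words to retain; the column
#'   order of the result follows `keep`.
#' @return the trimmed `dw_matrix`.
#' @export
trim_columns <- function(dw, keep) {
  keep <- as.character(keep)
  if (!length(keep)) stop("keep must name at least one word")
  missing <- setdiff(keep, colnames(dw))
  if (length(missing))
    stop("words not in the matrix vocabulary: ", paste(missing, collapse = ", "))
  out <- dw[, keep, drop = FALSE]
  attr(out, "degenerate") <- attr(dw, "degenerate")
  class(out) <- c("dw_matrix", class(unclass(out)))
  out
}
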
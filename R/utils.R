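# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never clobber
# the user's stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

sigmoid <- function(x) stats::plogis(x)

# Split-chain potential scale reduction factor. `chains` is a list of
# iter x p draw matrices; each chain is split in half before the usual
# between/within variance ratio. Returns one value per parameter.
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    h <- n %/% 2L
    halves[[length(halves) + 1L]] <- ch[seq_len(h), , drop = FALSE]
    halves[[length(halves) + 1L]] <- ch[(n - h + 1L):n, , drop = FALSE]
  }
  m <- length(halves)
  n <- nrow(halves[[1L]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1L]])))
  vars <- vapply(halves, function(h) apply(h, 2L, stats::var),
                 numeric(ncol(halves[[1L]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  b <- n * apply(means, 1L, stats::var)
  w <- rowMeans(vars)
  vhat <- (n - 1) / n * w + b / n
  out <- sqrt(vhat / w)
  out[w <= .Machine$double.eps] <- 1
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

record_ids <- function(records) {
  paste0(records$patient_id, "::", format(records$date, "%Y-%m-%d"))
}
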
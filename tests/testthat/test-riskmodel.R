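test_that("SMOTE balances classes with convex synthetic minority rows", {
  set.seed(5)
  X <- rbind(matrix(rnorm(10 * 3), 10, 3),          # minority
             matrix(rnorm(40 * 3, mean = 3), 40, 3)) # majority
  y <- c(rep(1, 10), rep(0, 40))
  out <- oversample_minority(X, y, k_neighbors = 5, seed = 2)
  expect_equal(as.integer(table(out$y)), c(40L, 40L))
  # originals retained unchanged, in place
  expect_identical(out$X[1:50, ], X)

  # convexity oracle: every synthetic row sits on a segment between two
  # minority rows (brute force over all pairs)
  M <- X[1:10, ]
  syn <- out$X[-(1:50), , drop = FALSE]
  on_segment <- function(s) {
    for (i in 1:9) for (j in (i + 1):10) {
      d <- M[j, ] - M[i, ]
      if (sum(d^2) < 1e-12) next
      t <- sum((s - M[i, ]) * d) / sum(d^2)
      if (t >= -1e-8 && t <= 1 + 1e-8 &&
          sqrt(sum((M[i, ] + t * d - s)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))

  # already balanced input returned unchanged
  bal <- oversample_minority(X[1:20, ], rep(0:1, each = 10), seed = 1)
  expect_identical(bal$X, X[1:20, ])
  expect_error(oversample_minority(X, rep(1, 50)), "both classes")
  expect_error(oversample_minority(X, c(rep(1, 4), rep(0, 46)), k_neighbors = 5),
               "k_neighbors")
})

test_that("posterior recovers known coefficients on simulated logistic data", {
  set.seed(11)
  n <- 2000; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(1.0, -0.7, 0.4, 0, 0.9)
  y <- rbinom(n, 1, plogis(0.2 + drop(X %*% beta)))
  fit <- fit_bayesian_logistic(X, y, prior_sd = 1, seed = 7)
  est <- fit$coefficients
  sds <- fit$posterior_sd[names(est)]
  expect_true(all(abs(est - beta) < 3 * sds))
  expect_lt(fit$max_rhat, 1.05)
  expect_gte(nrow(fit$posterior), 1000)
})

test_that("a flat likelihood returns the prior; separation is shrunk by it", {
  # all-zero feature: likelihood carries no information about its weight
  set.seed(2)
  X <- cbind(flat = rep(0, 400))
  y <- rep(0:1, 200)
  fit <- fit_bayesian_logistic(X, y, prior_sd = 1, intercept = FALSE,
                               chains = 2, warmup = 200, iter = 500, seed = 3)
  expect_lt(abs(fit$coefficients["flat"]), 0.15)
  expect_equal(unname(fit$posterior_sd["flat"]), 1, tolerance = 0.12)

  # perfectly separated one-feature data: quadrature oracle for the 1-D
  # posterior mean under the same prior
  xs <- c(rep(-1, 20), rep(1, 20))
  ys <- c(rep(0, 20), rep(1, 20))
  fit1 <- fit_bayesian_logistic(cbind(x = xs), ys, prior_sd = 1,
                                intercept = FALSE, chains = 2,
                                warmup = 300, iter = 1000, seed = 5)
  loglik <- function(b) vapply(b, function(bb)
    sum(dbinom(ys, 1, plogis(bb * xs), log = TRUE)), numeric(1))
  post <- function(b) exp(loglik(b) + dnorm(b, 0, 1, log = TRUE))
  z <- integrate(post, -10, 10)$value
  mean_oracle <- integrate(function(b) b * post(b) / z, -10, 10)$value
  expect_lt(abs(fit1$coefficients["x"]), 3 * 1)  # bounded by the prior
  expect_equal(unname(fit1$coefficients["x"]), mean_oracle, tolerance = 0.1)
})

test_that("posterior means shrink toward zero as the prior tightens", {
  set.seed(4)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * x))
  est <- vapply(c(0.1, 1, 10), function(ps) {
    abs(fit_bayesian_logistic(cbind(x = x), y, prior_sd = ps, chains = 1,
                              warmup = 200, iter = 500, seed = 8)$coefficients["x"])
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("risk probabilities follow the logistic closed form and its symmetries", {
  m <- structure(list(coefficients = c(a = 1, b = -1), intercept = 0,
                      vocabulary = c("a", "b"), has_intercept = TRUE,
                      center = NULL, scale = NULL),
                 class = "logistic_risk_model")
  X <- matrix(c(2, 1), 1, dimnames = list(NULL, c("a", "b")))
  expect_equal(unname(predict_risk(m, X)), plogis(1), tolerance = 1e-12)

  m0 <- m; m0$coefficients[] <- 0
  expect_equal(unname(predict_risk(m0, X)), 0.5)

  # monotone in a positively weighted feature
  X2 <- X; X2[1, "a"] <- 3
  expect_gt(predict_risk(m, X2), predict_risk(m, X))

  # sign symmetry: negating weights and intercept flips the probability
  mneg <- m; mneg$coefficients <- -m$coefficients; mneg$intercept <- -m$intercept
  expect_equal(unname(predict_risk(mneg, X)), 1 - unname(predict_risk(m, X)))

  expect_error(predict_risk(m, matrix(0, 1, 3)), "width|missing")

  # degenerate rows get the neutral probability
  Xd <- matrix(rnorm(4), 2, dimnames = list(NULL, c("a", "b")))
  attr(Xd, "degenerate") <- c(FALSE, TRUE)
  expect_equal(unname(predict_risk(m, Xd)[2]), 0.5)
})

test_that("credible-interval significance matches a sort-based quantile oracle", {
  set.seed(9)
  draws <- cbind(pos = rnorm(800, 1.2, 0.4),    # clearly positive
                 sym = rnorm(800, 0, 0.5),      # symmetric about zero
                 neg = rnorm(800, -0.8, 0.35))
  m <- structure(list(posterior = draws, vocabulary = colnames(draws)),
                 class = "logistic_risk_model")
  sig <- significant_words(m, 0.95)
  oracle <- colnames(draws)[vapply(colnames(draws), function(w) {
    s <- sort(draws[, w])
    lo <- s[ceiling(0.025 * length(s))]
    hi <- s[floor(0.975 * length(s)) + 1]
    lo > 0 || hi < 0
  }, logical(1))]
  expect_setequal(sig, oracle)
  expect_true("pos" %in% sig && "neg" %in% sig)
  expect_false("sym" %in% sig)

  tiny <- m; tiny$posterior <- draws[1:10, , drop = FALSE]
  expect_error(significant_words(tiny, 0.999), "too few")
})

test_that("vocabulary selection applies the at-least-k-of-n rule", {
  counts <- structure(c(a = 6L, b = 4L, c = 3L, d = 0L),
                      n_models = 6L, level = 0.95,
                      class = "significance_tally")
  expect_identical(select_vocabulary(counts, 4), c("a", "b"))
  expect_warning(out <- select_vocabulary(counts, 7), "exceeds")
  expect_length(out, 0)
  # brute-force filter oracle
  for (k in 0:6)
    expect_identical(select_vocabulary(counts, k),
                     names(counts)[unclass(counts) >= k])
})

test_that("the bisection ensemble tallies six models and respects word absence", {
  gen <- generate_corpus(small_gen_config(41))
  cp <- fallrisk:::prepare_corpus(gen$corpus, tiny_config())
  tally <- run_bisection_ensemble(cp, tiny_config(), seed = 3)
  expect_s3_class(tally, "significance_tally")
  expect_equal(attr(tally, "n_models"), 6L)
  expect_true(all(tally >= 0 & tally <= 6))
  # strong planted risk tokens dominate the top of the tally
  top <- names(sort(tally, decreasing = TRUE))[1:8]
  expect_gt(mean(grepl("^(risk|prot)", top)), 0.5)
})

test_that("the final model is the trimmed refit with the selected vocabulary", {
  gen <- generate_corpus(small_gen_config(43))
  cfg <- tiny_config()
  cp <- fallrisk:::prepare_corpus(gen$corpus, cfg)
  vocab <- build_vocabulary(cp, cfg$top_k)
  emb <- train_embeddings(cp, vocab, fallrisk:::as_embedding_config(cfg, 2))
  dw <- compute_dw(emb$D, emb$W)
  selected <- c("risk01", "risk02", "prot01", "w0003")
  m <- build_final_model(cp, selected, cfg, seed = 4, dw = dw)
  expect_identical(m$vocabulary, selected)
  expect_length(m$coefficients, 4L)
  expect_error(build_final_model(cp, character(), cfg, seed = 4, dw = dw),
               "empty")
})
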
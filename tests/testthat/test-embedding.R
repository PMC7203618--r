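test_that("vocabulary takes the most frequent tokens with lexicographic ties", {
  pat <- toy_patients()[3, , drop = FALSE]
  mk <- function(tokens) {
    rec <- data.frame(patient_id = "C", date = as.Date("2024-01-01"),
                      stringsAsFactors = FALSE)
    rec$tokens <- list(tokens)
    nursing_corpus(pat, rec)
  }
  cp <- mk(c(rep("a", 5), rep("b", 3), "c"))
  expect_identical(build_vocabulary(cp, 2)$word, c("a", "b"))
  expect_identical(build_vocabulary(cp, 10)$word, c("a", "b", "c"))

  # tie at the cutoff: brute-force full sort oracle
  toks <- c(rep("zed", 4), rep("ant", 2), rep("mid", 2), rep("bee", 2), "last")
  cp2 <- mk(toks)
  oracle <- {
    tab <- table(toks)
    df <- data.frame(w = names(tab), f = as.integer(tab), stringsAsFactors = FALSE)
    df <- df[order(-df$f, df$w), ]
    df$w[1:3]
  }
  expect_identical(build_vocabulary(cp2, 3)$word, oracle)
  expect_error(build_vocabulary(mk(character())), "not tokenized|empty")
})

test_that("vocabulary construction ignores record order", {
  gen <- generate_corpus(small_gen_config(31))
  cp <- gen$corpus
  shuffled <- cp
  perm <- rev(seq_len(nrow(cp$records)))
  shuffled$records <- cp$records[perm, , drop = FALSE]
  expect_identical(build_vocabulary(cp, 50), build_vocabulary(shuffled, 50))
})

test_that("embedding training is reproducible and shaped by the config", {
  gen <- generate_corpus(small_gen_config(33))
  cp <- gen$corpus
  vocab <- build_vocabulary(cp, 60)
  cfg <- embedding_config(dim = 20, epochs = 2, window = 2, seed = 9)
  e1 <- train_embeddings(cp, vocab, cfg)
  e2 <- train_embeddings(cp, vocab, cfg)
  expect_identical(unclass(e1$W), unclass(e2$W))
  expect_identical(e1$D, e2$D)
  expect_equal(dim(e1$W), c(nrow(vocab), 20))
  expect_equal(dim(e1$D), c(nrow(cp$records), 20))
  expect_true(all(is.finite(e1$W)))
  e3 <- train_embeddings(cp, vocab, embedding_config(dim = 20, epochs = 2,
                                                     window = 2, seed = 10))
  expect_false(identical(unclass(e1$W), unclass(e3$W)))
  # the convenience wrappers agree with the joint trainer
  expect_identical(unclass(train_word_embeddings(cp, vocab, cfg)), unclass(e1$W))
  expect_identical(train_doc_embeddings(cp, vocab, cfg), e1$D)
})

test_that("words sharing contexts embed closer than words that never do", {
  # two interleaved sublanguages: {x, y} always co-occur within topic-1
  # sentences, z only ever appears with topic-2 fillers
  pat <- toy_patients()[3, , drop = FALSE]
  set.seed(42)
  n <- 120
  rec <- data.frame(patient_id = "C", date = as.Date("2024-01-01") + seq_len(n),
                    stringsAsFactors = FALSE)
  rec$tokens <- lapply(seq_len(n), function(i) {
    if (i %% 2 == 0) {
      as.vector(rbind(sample(c("x", "y"), 6, TRUE), sample(paste0("f", 1:4), 6, TRUE)))
    } else {
      as.vector(rbind(sample(c("z", "w"), 6, TRUE), sample(paste0("g", 1:4), 6, TRUE)))
    }
  })
  cp <- nursing_corpus(pat, rec)
  vocab <- build_vocabulary(cp, 50)
  W <- train_word_embeddings(cp, vocab, embedding_config(dim = 16, epochs = 20,
                                                         window = 3, seed = 4))
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_gt(cosine(W["x", ], W["y", ]), cosine(W["x", ], W["z", ]))
})

test_that("same-topic documents embed closer than cross-topic documents", {
  pat <- toy_patients()[3, , drop = FALSE]
  set.seed(7)
  rec <- data.frame(patient_id = "C", date = as.Date("2024-01-01") + 1:40,
                    stringsAsFactors = FALSE)
  topicA <- paste0("a", 1:6); topicB <- paste0("b", 1:6)
  rec$tokens <- lapply(1:40, function(i) {
    if (i <= 20) sample(topicA, 12, TRUE) else sample(topicB, 12, TRUE)
  })
  cp <- nursing_corpus(pat, rec)
  vocab <- build_vocabulary(cp, 20)
  emb <- train_embeddings(cp, vocab, embedding_config(dim = 16, epochs = 10,
                                                      window = 2, seed = 5))
  D <- emb$D
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  within <- cosine(D[1, ], D[2, ])
  across <- cosine(D[1, ], D[30, ])
  expect_gt(within, across)
})

test_that("document-word product matches brute-force inner products and is bilinear", {
  set.seed(1)
  for (trial in 1:5) {
    m <- sample(1:10, 1); n <- sample(1:10, 1); k <- sample(1:10, 1)
    D <- matrix(rnorm(m * k), m, k)
    W <- matrix(rnorm(n * k), n, k)
    rownames(W) <- paste0("w", seq_len(n))
    dw <- compute_dw(D, W)
    oracle <- matrix(0, m, n)
    for (i in seq_len(m)) for (j in seq_len(n))
      oracle[i, j] <- sum(D[i, ] * W[j, ])
    expect_equal(unclass(dw), oracle, ignore_attr = TRUE)
    # bilinearity
    a <- 2.5
    expect_equal(unclass(compute_dw(a * D, W)), a * unclass(dw), ignore_attr = TRUE)
    W2 <- matrix(rnorm(n * k), n, k, dimnames = list(rownames(W), NULL))
    expect_equal(unclass(compute_dw(D, W + W2)),
                 unclass(dw) + unclass(compute_dw(D, W2)), ignore_attr = TRUE)
  }
  expect_equal(unclass(compute_dw(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                                  matrix(c(2, 0, 0, 3), 2, byrow = TRUE))),
               matrix(c(2, 0, 0, 3), 2, byrow = TRUE), ignore_attr = TRUE)
  expect_equal(unclass(compute_dw(matrix(c(1, 2), 1), matrix(c(3, -1), 1)))[1, 1], 1)
  expect_error(compute_dw(matrix(0, 2, 3), matrix(0, 2, 4)), "mismatch")
})

test_that("word-analogy linearity carries over to the document-word matrix", {
  set.seed(3)
  k <- 8
  W <- matrix(rnorm(4 * k), 4, k)
  W[4, ] <- W[3, ] - W[1, ] + W[2, ]  # w1 - w2 = w3 - w4
  rownames(W) <- paste0("w", 1:4)
  D <- matrix(rnorm(6 * k), 6, k)
  dw <- unclass(compute_dw(D, W))
  expect_equal(dw[, 1] - dw[, 2], dw[, 3] - dw[, 4])
})

test_that("column trimming preserves order and rejects unknown or empty sets", {
  D <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("w", 1:5), NULL))
  dw <- compute_dw(D, W)
  expect_identical(colnames(trim_columns(dw, c("w3", "w1"))), c("w3", "w1"))
  expect_equal(unclass(trim_columns(dw, rownames(W))), unclass(dw),
               ignore_attr = TRUE)
  expect_error(trim_columns(dw, c("w1", "nope")), "not in the matrix")
  expect_error(trim_columns(dw, character()), "at least one word")
  # trimming commutes with computing the product on the kept rows of W
  keep <- c("w2", "w5")
  expect_equal(unclass(trim_columns(dw, keep)),
               unclass(compute_dw(D, W[keep, , drop = FALSE])),
               ignore_attr = TRUE)
})

test_that("inference reproduces training vectors and flags degenerate documents", {
  gen <- generate_corpus(small_gen_config(35))
  cp <- gen$corpus
  vocab <- build_vocabulary(cp, 60)
  cfg <- embedding_config(dim = 64, epochs = 2, window = 1, seed = 9)
  emb <- train_embeddings(cp, vocab, cfg)
  inferred <- infer_doc_vectors(cp, vocab, emb$W, cfg)
  # the deterministic solution makes re-inference exact, so every training
  # document retrieves itself
  expect_equal(inferred, emb$D, tolerance = 1e-10, ignore_attr = TRUE)

  # document with no in-vocabulary overlap
  extra <- cp
  new_rec <- extra$records[1, , drop = FALSE]
  new_rec$date <- max(extra$records$date) + 1
  new_rec$tokens <- list(c("outofvocab1", "outofvocab2"))
  extra$records <- new_rec
  iv <- infer_doc_vectors(extra, vocab, emb$W, cfg)
  expect_true(attr(iv, "degenerate"))
  expect_equal(as.numeric(iv), rep(0, ncol(iv)))

  # determinism
  expect_identical(infer_doc_vectors(cp, vocab, emb$W, cfg), inferred)
})
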
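# Fixture builders shared across the test files. All corpora are built in
# code; nothing is read from disk.

toy_patients <- function() {
  data.frame(
    patient_id = c("A", "B", "C", "D"),
    label = c("faller", "faller", "nonfaller", "nonfaller"),
    fall_dates = I(list(as.Date("2024-01-10"),
                        as.Date(c("2024-01-10", "2024-01-30")),
                        as.Date(character()), as.Date(character()))),
    stringsAsFactors = FALSE
  )
}

toy_corpus <- function() {
  pat <- toy_patients()
  rec <- data.frame(
    patient_id = c("A", "A", "A", "B", "C", "D"),
    date = as.Date(c("2024-01-03", "2024-01-09", "2024-01-02",
                     "2024-01-25", "2024-01-05", "2024-01-06")),
    stringsAsFactors = FALSE
  )
  rec$tokens <- list(
    c("fell", "night", "restless", "assistance", "wheelchair", "transfer"),
    c("unsteady", "gait", "dizzy", "assistance", "nurse", "call"),
    c("sleeping", "quiet", "comfortable", "stable", "vitals", "normal"),
    c("confusion", "wandering", "restless", "sedative", "night", "check"),
    c("stable", "comfortable", "reading", "visitors", "afternoon", "tea"),
    c("walking", "independent", "discharge", "planning", "stable", "well")
  )
  nursing_corpus(pat, rec)
}

# a small synthetic corpus for pipeline-level tests; strong signal so even
# tiny embeddings separate the classes
small_gen_config <- function(seed, ...) {
  args <- list(n_fallers = 20L, n_nonfallers = 25L, vocab_size = 150L,
               n_risk_tokens = 8L, n_protective_tokens = 4L,
               n_precursor_tokens = 5L, effect_log_odds = 1.5,
               records_mean_faller = 14, records_mean_nonfaller = 9,
               tokens_per_record = 40, planted_rank = 10L, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(generator_config, args)
}

# pipeline settings small enough for unit tests
tiny_config <- function(...) {
  benchmark_config(dim = 96L, epochs = 2L, top_k = 80L,
                   warmup = 200L, iter = 600L, L_max = 5L, smote_k = 3L, ...)
}
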
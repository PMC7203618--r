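test_that("corpus construction enforces referential and label invariants", {
  pat <- toy_patients()
  rec <- toy_corpus()$records

  expect_s3_class(nursing_corpus(pat, rec), "nursing_corpus")

  bad <- rec
  bad$patient_id[1] <- "ZZZ"
  expect_error(nursing_corpus(pat, bad), "unknown patient_id")

  dup <- rbind(pat, pat[1, ])
  expect_error(nursing_corpus(dup, rec), "duplicate patient_id")

  mislabeled <- pat
  mislabeled$fall_dates[[3]] <- as.Date("2024-01-05")
  expect_error(nursing_corpus(mislabeled, rec), "nonfaller .* fall dates")

  nofall <- pat
  nofall$fall_dates[[1]] <- as.Date(character())
  expect_error(nursing_corpus(nofall, rec), "no fall dates")

  unsorted <- pat
  unsorted$fall_dates[[2]] <- as.Date(c("2024-01-30", "2024-01-10"))
  expect_error(nursing_corpus(unsorted, rec), "strictly increasing")
})

test_that("write_corpus / read_corpus round-trips a corpus exactly", {
  cp <- toy_corpus()
  cp$provenance <- c("step one", "step two")
  dir <- withr::local_tempdir()
  write_corpus(cp, dir)
  back <- read_corpus(dir)
  expect_identical(back$records$patient_id, cp$records$patient_id)
  expect_identical(back$records$date, cp$records$date)
  expect_identical(back$records$tokens, cp$records$tokens)
  expect_identical(back$records$char_count, cp$records$char_count)
  expect_identical(back$patients$label, cp$patients$label)
  expect_identical(back$patients$fall_dates, cp$patients$fall_dates)
  expect_identical(back$provenance, cp$provenance)

  # malformed record line is reported with its line number
  lines <- readLines(file.path(dir, "records.tsv"))
  lines[3] <- paste(lines[3], "extra", "fields", sep = "\t")
  writeLines(lines, file.path(dir, "records.tsv"))
  expect_error(read_corpus(dir), "line 3")
})

test_that("raw-text records tokenize through the pluggable tokenizer", {
  pat <- toy_patients()[3, , drop = FALSE]
  rec <- data.frame(patient_id = "C", date = as.Date("2024-01-05"),
                    stringsAsFactors = FALSE)
  rec$tokens <- list(character())
  rec$text <- "patient resting  comfortably tonight"
  cp <- nursing_corpus(pat, rec)
  expect_equal(cp$records$char_count, nchar("patientrestingcomfortablytonight"))
  cp <- tokenize_corpus(cp)
  expect_identical(cp$records$tokens[[1]],
                   c("patient", "resting", "comfortably", "tonight"))
})

test_that("same-day records are integrated with summed counts, idempotently", {
  pat <- toy_patients()[1:2, , drop = FALSE]
  rec <- data.frame(
    patient_id = c("A", "A", "A", "A"),
    date = as.Date(c("2024-01-03", "2024-01-03", "2024-01-03", "2024-01-04")),
    stringsAsFactors = FALSE)
  rec$tokens <- list(c("x", "y"), c("z"), c("w"), c("q"))
  rec$char_count <- c(30L, 25L, 10L, 5L)
  pat <- pat[pat$patient_id == "A", , drop = FALSE]
  cp <- nursing_corpus(pat, rec)

  merged <- integrate_daily_records(cp)
  expect_equal(nrow(merged$records), 2L)
  day1 <- merged$records[merged$records$date == as.Date("2024-01-03"), ]
  expect_identical(day1$tokens[[1]], c("x", "y", "z", "w"))
  expect_equal(day1$char_count, 30L + 25L + 10L)

  again <- integrate_daily_records(merged)
  expect_identical(again$records, merged$records)

  single <- nursing_corpus(pat, rec[4, , drop = FALSE])
  expect_identical(integrate_daily_records(single)$records, single$records)
})

test_that("short-record exclusion keeps records strictly above the threshold", {
  pat <- toy_patients()[3, , drop = FALSE]
  rec <- data.frame(patient_id = rep("C", 3),
                    date = as.Date("2024-01-01") + 0:2,
                    stringsAsFactors = FALSE)
  rec$tokens <- list(character(), character(), character())
  rec$char_count <- c(50L, 51L, 200L)
  cp <- nursing_corpus(pat, rec)
  kept <- filter_short_records(cp, 50)
  expect_equal(kept$records$char_count, c(51L, 200L))

  # brute-force check over counts 1..10
  rec10 <- data.frame(patient_id = rep("C", 10),
                      date = as.Date("2024-01-01") + 0:9,
                      stringsAsFactors = FALSE)
  rec10$tokens <- replicate(10, character(), simplify = FALSE)
  rec10$char_count <- 1:10
  cp10 <- nursing_corpus(pat, rec10)
  expect_equal(nrow(filter_short_records(cp10, 5)$records),
               sum((1:10) > 5))

  empty <- cp
  empty$records <- cp$records[0, , drop = FALSE]
  expect_equal(nrow(filter_short_records(empty, 50)$records), 0L)
  expect_error(filter_short_records(cp, -1), "non-negative")
})

test_that("imminent tagging follows the pre-fall window for every fall", {
  pat <- toy_patients()
  rec <- data.frame(
    patient_id = c("A", "A", "A", "A", "B", "C"),
    date = as.Date(c("2024-01-02", "2024-01-03", "2024-01-09", "2024-01-10",
                     "2024-01-25", "2024-01-05")),
    stringsAsFactors = FALSE)
  rec$tokens <- replicate(6, c("tok"), simplify = FALSE)
  cp <- nursing_corpus(pat, rec)

  tagged <- tag_imminent(cp, window_days = 7)
  imm <- tagged$records$imminent
  # A falls on day 10: days 3 and 9 imminent; day 2 and the fall day not
  expect_identical(imm[1:4], c("not_imminent", "imminent", "imminent", "not_imminent"))
  # B falls on days 10 and 30: day 25 is in the second window
  expect_identical(imm[5], "imminent")
  expect_identical(imm[6], "untagged")

  with_day <- tag_imminent(cp, window_days = 7, include_fall_day = TRUE)
  expect_identical(with_day$records$imminent[4], "imminent")
  expect_error(tag_imminent(cp, window_days = 0), ">= 1")

  # window covering no record dates marks nothing imminent
  far <- tag_imminent(cp, window_days = 1)
  expect_false(any(far$records$imminent[1:2] == "imminent"))
})

test_that("stay stratification splits fallers at the record-count bounds", {
  pat <- data.frame(patient_id = c("L", "S", "M", "N"),
                    label = c("faller", "faller", "faller", "nonfaller"),
                    stringsAsFactors = FALSE)
  pat$fall_dates <- list(as.Date("2024-03-01"), as.Date("2024-01-02"),
                         as.Date("2024-02-01"), as.Date(character()))
  counts <- c(L = 61, S = 45, M = 50, N = 10)
  rec <- do.call(rbind, lapply(names(counts), function(id) {
    data.frame(patient_id = id, date = as.Date("2024-01-01") + seq_len(counts[[id]]) - 1,
               stringsAsFactors = FALSE)
  }))
  rec$tokens <- replicate(nrow(rec), "tok", simplify = FALSE)
  cp <- nursing_corpus(pat, rec)

  strata <- stratify_by_stay(cp)
  expect_identical(strata$long$patients$patient_id, "L")
  expect_identical(strata$short$patients$patient_id, "S")
  expect_identical(strata$unassigned$patients$patient_id, "M")
  # nonfallers appear in no stratum
  expect_false("N" %in% unlist(lapply(strata, function(s) s$patients$patient_id)))
  expect_error(stratify_by_stay(cp, long_min = 40, short_max = 45), "exceed")
})

test_that("patient splits are deterministic, sized by floor, and partition records", {
  gen <- generate_corpus(small_gen_config(5))
  cp <- gen$corpus
  s1 <- split_patients(cp, 0.5, seed = 11)
  s2 <- split_patients(cp, 0.5, seed = 11)
  expect_identical(s1$part1$patients$patient_id, s2$part1$patients$patient_id)

  # stratified halving: floor per class
  expect_equal(sum(s1$part1$patients$label == "faller"), 10L)
  expect_equal(sum(s1$part1$patients$label == "nonfaller"), 12L)

  ids1 <- record_ids_for <- paste(s1$part1$records$patient_id, s1$part1$records$date)
  ids2 <- paste(s1$part2$records$patient_id, s1$part2$records$date)
  all_ids <- paste(cp$records$patient_id, cp$records$date)
  expect_setequal(c(ids1, ids2), all_ids)
  expect_length(intersect(s1$part1$patients$patient_id,
                          s2$part2$patients$patient_id), 0L)

  expect_error(split_patients(cp, 1.2, seed = 1), "fraction")

  # unstratified: first part floor(fraction * n)
  u <- split_patients(cp, 0.4, seed = 3, stratify = FALSE)
  expect_equal(nrow(u$part1$patients), floor(0.4 * nrow(cp$patients)))
})
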
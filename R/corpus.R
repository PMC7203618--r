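#' Construct a nursing-record corpus
#'
#' A corpus bundles a patient table (the case-control frame: one row per
#' patient with a faller/nonfaller label and, for fallers, the fall dates)
#' with the per-patient per-day nursing records that the embedding and risk
#' models consume. Records may carry raw free text (tokenized later through a
#' pluggable tokenizer) or a pre-tokenized token vector.
#'
#' @param patients data.frame with columns `patient_id`, `label`
#'   (`"faller"`/`"nonfaller"`), `fall_dates` (list column of `Date`,
#'   empty for nonfallers), and optionally `age`, `sex`, `division`.
#' @param records data.frame with columns `patient_id`, `date` (`Date`),
#'   `tokens` (list column of character vectors; may be empty when `text`
#'   is supplied), and optionally `text`, `char_count`, `imminent`.
#' @param provenance character vector logging the transforms applied so far.
#'
#' @details Invariants enforced: patient ids are unique; a patient is a
#' faller if and only if it has at least one fall date; fall dates are
#' strictly increasing; every record references a known patient. The
#' character count used by the exclusion filter is the number of
#' non-whitespace characters for raw text, and the total token length for
#' pre-tokenized records (a script-agnostic proxy for the ideographic
#' character counts of the original notes).
#'
#' @return An object of class `nursing_corpus`.
#' @export
nursing_corpus <- function(patients, records, provenance = character()) {
  stopifnot(is.data.frame(patients), is.data.frame(records))
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  req_p <- c("patient_id", "label", "fall_dates")
  miss <- setdiff(req_p, names(patients))
  if (length(miss)) stop("patient table missing columns: ", paste(miss, collapse = ", "))
  patients$patient_id <- as.character(patients$patient_id)
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patient table: ",
         paste(unique(patients$patient_id[duplicated(patients$patient_id)]), collapse = ", "))
  if (!all(patients$label %in% c("faller", "nonfaller")))
    stop("patient label must be 'faller' or 'nonfaller'")
  if (!is.list(patients$fall_dates))
    stop("fall_dates must be a list column of Date vectors")
  patients$fall_dates <- lapply(patients$fall_dates, function(d) {
    d <- as.Date(d)
    d[!is.na(d)]
  })
  for (i in seq_len(nrow(patients))) {
    fd <- patients$fall_dates[[i]]
    lab <- patients$label[i]
    if (lab == "faller" && length(fd) == 0L)
      stop("faller ", patients$patient_id[i], " has no fall dates")
    if (lab == "nonfaller" && length(fd) > 0L)
      stop("nonfaller ", patients$patient_id[i], " has fall dates")
    if (length(fd) > 1L && any(diff(fd) <= 0))
      stop("fall dates for ", patients$patient_id[i], " are not strictly increasing")
  }
  for (opt in c("age", "sex", "division")) {
    if (is.null(patients[[opt]])) patients[[opt]] <- rep(NA, nrow(patients))
  }

  req_r <- c("patient_id", "date")
  miss <- setdiff(req_r, names(records))
  if (length(miss)) stop("record table missing columns: ", paste(miss, collapse = ", "))
  records$patient_id <- as.character(records$patient_id)
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) stop("records contain unparseable dates")
  unknown <- setdiff(records$patient_id, patients$patient_id)
  if (length(unknown))
    stop("records reference unknown patient_id: ", paste(unknown, collapse = ", "))
  if (is.null(records$tokens)) records$tokens <- replicate(nrow(records), character(), simplify = FALSE)
  if (!is.list(records$tokens)) stop("tokens must be a list column of character vectors")
  records$tokens <- lapply(records$tokens, as.character)
  if (is.null(records$text)) records$text <- rep(NA_character_, nrow(records))
  records$text <- as.character(records$text)
  if (is.null(records$imminent)) records$imminent <- rep("untagged", nrow(records))
  if (!all(records$imminent %in% c("imminent", "not_imminent", "untagged")))
    stop("imminent tag must be one of imminent/not_imminent/untagged")
  if (is.null(records$char_count)) records$char_count <- rep(NA_integer_, nrow(records))
  need <- is.na(records$char_count)
  if (any(need)) records$char_count[need] <- compute_char_count(records[need, , drop = FALSE])
  records$char_count <- as.integer(records$char_count)
  if (any(records$char_count < 0, na.rm = TRUE)) stop("negative char_count")

  structure(
    list(patients = patients, records = records,
         provenance = as.character(provenance)),
    class = "nursing_corpus"
  )
}

compute_char_count <- function(records) {
  vapply(seq_len(nrow(records)), function(i) {
    tk <- records$tokens[[i]]
    if (length(tk)) {
      sum(nchar(tk))
    } else if (!is.na(records$text[i])) {
      nchar(gsub("\\s", "", records$text[i]))
    } else 0L
  }, integer(1))
}

#' @export
print.nursing_corpus <- function(x, ...) {
  np <- nrow(x$patients)
  nf <- sum(x$patients$label == "faller")
  cat("Nursing-record corpus\n")
  cat(sprintf("  patients: %d (%d fallers, %d nonfallers)\n", np, nf, np - nf))
  cat(sprintf("  records:  %d\n", nrow(x$records)))
  tagged <- x$records$imminent != "untagged"
  if (any(tagged))
    cat(sprintf("  imminent tags: %d imminent / %d not imminent\n",
                sum(x$records$imminent == "imminent"),
                sum(x$records$imminent == "not_imminent")))
  if (length(x$provenance))
    cat("  provenance:", length(x$provenance), "entries\n")
  invisible(x)
}

log_provenance <- function(corpus, msg) {
  corpus$provenance <- c(corpus$provenance, msg)
  corpus
}

#' Whitespace tokenizer
#'
#' Default tokenizer for raw record text: splits on runs of whitespace.
#' Morphological analyzers for specific languages can be supplied to
#' [tokenize_corpus()] as any function mapping one string to a character
#' vector of tokens.
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
whitespace_tokenizer <- function(text) {
  out <- strsplit(trimws(text), "\\s+")[[1]]
  out[nzchar(out)]
}

#' Tokenize raw record text
#'
#' Applies `tokenizer` to every record that carries raw text but no tokens.
#' Records already tokenized are left untouched; `char_count` keeps its
#' original (raw-text) value.
#'
#' @param corpus a `nursing_corpus`.
#' @param tokenizer function from one string to a character vector.
#' @return the corpus with all records tokenized.
#' @export
tokenize_corpus <- function(corpus, tokenizer = whitespace_tokenizer) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  need <- lengths(corpus$records$tokens) == 0L & !is.na(corpus$records$text)
  corpus$records$tokens[need] <- lapply(corpus$records$text[need], tokenizer)
  log_provenance(corpus, sprintf("tokenized %d raw-text records", sum(need)))
}

#' Read a corpus from delimited text files
#'
#' @param records_path path to the tab-separated records file, or a directory
#'   containing `records.tsv`, `patients.tsv` and optionally
#'   `provenance.txt` as written by [write_corpus()].
#' @param patients_path path to the tab-separated patient table (ignored when
#'   `records_path` is a directory).
#'
#' @details The records file has a header line and one record per line with
#' fields `patient_id`, `date` (ISO-8601), `tokens` (space-joined; empty for
#' raw text records), `text`, `char_count`, `imminent`, `division`. The
#' patient table has fields `patient_id`, `label`, `fall_dates`
#' (semicolon-joined ISO dates), `age`, `sex`, `division`. Malformed lines
#' are reported with their line number.
#'
#' @return a `nursing_corpus`.
#' @export
read_corpus <- function(records_path, patients_path = NULL) {
  if (dir.exists(records_path)) {
    dir <- records_path
    records_path <- file.path(dir, "records.tsv")
    patients_path <- file.path(dir, "patients.tsv")
    prov_path <- file.path(dir, "provenance.txt")
  } else {
    prov_path <- NULL
  }
  if (is.null(patients_path)) stop("patients_path required when records_path is a file")

  rec <- read_tsv_checked(records_path,
                          c("patient_id", "date", "tokens", "text",
                            "char_count", "imminent", "division"))
  pat <- read_tsv_checked(patients_path,
                          c("patient_id", "label", "fall_dates", "age",
                            "sex", "division"))

  bad <- which(is.na(suppressWarnings(as.Date(rec$date, format = "%Y-%m-%d"))))
  if (length(bad))
    stop("malformed date in ", records_path, " at line ", bad[1] + 1L)

  records <- data.frame(patient_id = rec$patient_id,
                        date = as.Date(rec$date),
                        stringsAsFactors = FALSE)
  records$tokens <- lapply(rec$tokens, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, " ", fixed = TRUE)[[1]]
  })
  records$text <- ifelse(is.na(rec$text) | !nzchar(rec$text), NA_character_, rec$text)
  records$char_count <- suppressWarnings(as.integer(rec$char_count))
  records$imminent <- ifelse(is.na(rec$imminent) | !nzchar(rec$imminent),
                             "untagged", rec$imminent)
  if (!is.null(rec$division)) records$division <- rec$division

  patients <- data.frame(patient_id = pat$patient_id,
                         label = pat$label, stringsAsFactors = FALSE)
  patients$fall_dates <- lapply(pat$fall_dates, function(s) {
    if (is.na(s) || !nzchar(s)) return(as.Date(character()))
    d <- as.Date(strsplit(s, ";", fixed = TRUE)[[1]])
    if (anyNA(d)) stop("malformed fall date string: ", s)
    d
  })
  patients$age <- suppressWarnings(as.numeric(pat$age))
  patients$sex <- ifelse(is.na(pat$sex) | !nzchar(pat$sex), "unknown", pat$sex)
  patients$division <- pat$division

  prov <- character()
  if (!is.null(prov_path) && file.exists(prov_path))
    prov <- readLines(prov_path, warn = FALSE)
  nursing_corpus(patients, records, provenance = prov)
}

read_tsv_checked <- function(path, expected) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  unknown <- setdiff(header, expected)
  if (length(unknown))
    stop("unexpected columns in ", path, ": ", paste(unknown, collapse = ", "))
  if (!all(c("patient_id") %in% header))
    stop("missing patient_id column in ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  nfield <- length(header)
  parts <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad, but flag lines with too many
  lens <- lengths(parts)
  bad <- which(lens > nfield)
  if (length(bad))
    stop("malformed line ", bad[1] + 1L, " in ", path, ": expected ",
         nfield, " fields, found ", lens[bad[1]])
  out <- lapply(seq_len(nfield), function(j) {
    vapply(parts, function(p) if (j <= length(p)) p[j] else "", character(1))
  })
  names(out) <- header
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  for (col in setdiff(expected, header)) df[[col]] <- NA_character_
  df[df == ""] <- NA
  df
}

#' Write a corpus to delimited text files
#'
#' Serializes into the same layout [read_corpus()] accepts: `records.tsv`,
#' `patients.tsv` and `provenance.txt` under `path`. Writing then re-reading
#' reproduces the corpus exactly.
#'
#' @param corpus a `nursing_corpus`.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path)
  }
  esc <- function(x) gsub("[\t\n\r]", " ", x)
  rec <- corpus$records
  rec_lines <- c(
    paste(c("patient_id", "date", "tokens", "text", "char_count",
            "imminent", "division"), collapse = "\t"),
    vapply(seq_len(nrow(rec)), function(i) {
      paste(c(rec$patient_id[i],
              format(rec$date[i], "%Y-%m-%d"),
              paste(rec$tokens[[i]], collapse = " "),
              if (is.na(rec$text[i])) "" else esc(rec$text[i]),
              rec$char_count[i],
              rec$imminent[i],
              if (is.null(rec$division) || is.na(rec$division[i])) "" else esc(rec$division[i])),
            collapse = "\t")
    }, character(1))
  )
  pat <- corpus$patients
  pat_lines <- c(
    paste(c("patient_id", "label", "fall_dates", "age", "sex", "division"),
          collapse = "\t"),
    vapply(seq_len(nrow(pat)), function(i) {
      paste(c(pat$patient_id[i],
              pat$label[i],
              paste(format(pat$fall_dates[[i]], "%Y-%m-%d"), collapse = ";"),
              if (is.na(pat$age[i])) "" else pat$age[i],
              if (is.na(pat$sex[i])) "" else pat$sex[i],
              if (is.na(pat$division[i])) "" else esc(pat$division[i])),
            collapse = "\t")
    }, character(1))
  )
  writeLines(rec_lines, file.path(path, "records.tsv"), useBytes = TRUE)
  writeLines(pat_lines, file.path(path, "patients.tsv"), useBytes = TRUE)
  writeLines(corpus$provenance, file.path(path, "provenance.txt"), useBytes = TRUE)
  invisible(path)
}

#' Integrate same-day records
#'
#' Several notes for one patient written on the same day are merged into a
#' single nursing record: token sequences are concatenated in input order,
#' raw texts pasted, and character counts summed. Idempotent.
#'
#' @param corpus a `nursing_corpus`.
#' @return the corpus with one record per (patient, day).
#' @export
integrate_daily_records <- function(corpus) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  rec <- corpus$records
  key <- paste(rec$patient_id, format(rec$date, "%Y-%m-%d"), sep = "\r")
  if (!anyDuplicated(key)) return(corpus)
  groups <- split(seq_len(nrow(rec)), factor(key, levels = unique(key)))
  merged <- lapply(groups, function(idx) {
    texts <- rec$text[idx]
    texts <- texts[!is.na(texts)]
    imm <- unique(rec$imminent[idx])
    data.frame(
      patient_id = rec$patient_id[idx[1]],
      date = rec$date[idx[1]],
      tokens = I(list(unlist(rec$tokens[idx], use.names = FALSE))),
      text = if (length(texts)) paste(texts, collapse = " ") else NA_character_,
      char_count = sum(rec$char_count[idx]),
      imminent = if (length(imm) == 1L) imm else "untagged",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  corpus$records <- out
  log_provenance(corpus, sprintf("integrated same-day records: %d -> %d",
                                 nrow(rec), nrow(out)))
}

#' Exclude short records
#'
#' Drops nursing records whose character count does not exceed `min_chars`
#' (strictly more than `min_chars` characters are required, mirroring the
#' usual exclusion of stub notes too short to carry clinical content).
#'
#' @param corpus a `nursing_corpus`.
#' @param min_chars minimum character count; a record is kept iff
#'   `char_count > min_chars`. Default 50.
#' @return the filtered corpus; the number of removed records per class is
#'   appended to the provenance log.
#' @export
filter_short_records <- function(corpus, min_chars = 50L) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (min_chars < 0) stop("min_chars must be non-negative")
  rec <- corpus$records
  keep <- rec$char_count > min_chars
  lab <- corpus$patients$label[match(rec$patient_id, corpus$patients$patient_id)]
  removed_f <- sum(!keep & lab == "faller")
  removed_n <- sum(!keep & lab == "nonfaller")
  corpus$records <- rec[keep, , drop = FALSE]
  rownames(corpus$records) <- NULL
  log_provenance(corpus, sprintf(
    "filtered records with char_count <= %d: removed %d faller, %d nonfaller",
    min_chars, removed_f, removed_n))
}

#' Tag records in the imminent pre-fall window
#'
#' Marks each faller record as `imminent` when its date falls within
#' `window_days` days before any of the patient's falls (1 to `window_days`
#' days before; the day of the fall itself is excluded unless
#' `include_fall_day`). All other faller records become `not_imminent`;
#' nonfaller records stay `untagged`.
#'
#' @param corpus a `nursing_corpus`.
#' @param window_days window length in days (default 7).
#' @param include_fall_day also count the day of the fall as imminent.
#' @return the tagged corpus.
#' @export
tag_imminent <- function(corpus, window_days = 7L, include_fall_day = FALSE) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (window_days < 1) stop("window_days must be >= 1")
  pat <- corpus$patients
  rec <- corpus$records
  fall_map <- stats::setNames(pat$fall_dates, pat$patient_id)
  lab_map <- stats::setNames(pat$label, pat$patient_id)
  hi_off <- if (include_fall_day) 0L else 1L
  rec$imminent <- vapply(seq_len(nrow(rec)), function(i) {
    pid <- rec$patient_id[i]
    if (lab_map[[pid]] != "faller") return("untagged")
    d <- rec$date[i]
    falls <- fall_map[[pid]]
    hit <- any(d >= falls - window_days & d <= falls - hi_off)
    if (hit) "imminent" else "not_imminent"
  }, character(1))
  corpus$records <- rec
  log_provenance(corpus, sprintf(
    "tagged imminent window [fall-%d, fall-%d]: %d imminent / %d not imminent",
    window_days, hi_off,
    sum(rec$imminent == "imminent"), sum(rec$imminent == "not_imminent")))
}

#' Stratify fallers by length of stay
#'
#' Partitions the faller patients by their record count (a proxy for length
#' of stay): long-stay (more than `long_min - 1` records), short-stay (at
#' most `short_max` records), and an unassigned middle band. Nonfaller
#' patients are dropped from all three strata.
#'
#' @param corpus a `nursing_corpus` (record counts are taken after any
#'   integration/filtering already applied).
#' @param long_min minimum record count of the long stratum (default 61,
#'   i.e. more than 60 records).
#' @param short_max maximum record count of the short stratum (default 45).
#' @return list with elements `long`, `short`, `unassigned`, each a corpus.
#' @export
stratify_by_stay <- function(corpus, long_min = 61L, short_max = 45L) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (long_min <= short_max) stop("long_min must exceed short_max")
  fallers <- corpus$patients$patient_id[corpus$patients$label == "faller"]
  counts <- table(factor(corpus$records$patient_id, levels = fallers))
  long_ids <- names(counts)[counts >= long_min]
  short_ids <- names(counts)[counts <= short_max]
  mid_ids <- setdiff(names(counts), c(long_ids, short_ids))
  list(long = subset_corpus(corpus, long_ids, "long-stay stratum"),
       short = subset_corpus(corpus, short_ids, "short-stay stratum"),
       unassigned = subset_corpus(corpus, mid_ids, "unassigned stratum"))
}

subset_corpus <- function(corpus, patient_ids, what = "subset") {
  keep_p <- corpus$patients$patient_id %in% patient_ids
  keep_r <- corpus$records$patient_id %in% patient_ids
  out <- corpus
  out$patients <- corpus$patients[keep_p, , drop = FALSE]
  out$records <- corpus$records[keep_r, , drop = FALSE]
  rownames(out$patients) <- rownames(out$records) <- NULL
  log_provenance(out, sprintf("%s: kept %d patients / %d records",
                              what, sum(keep_p), sum(keep_r)))
}

#' Split a corpus at the patient level
#'
#' Randomly partitions the patients into two disjoint groups (typically a
#' learning and a test set); every record follows its patient. The first
#' part receives `floor(fraction * n)` patients. With `stratify = TRUE`
#' (default) the split is performed within each class so that fallers and
#' nonfallers are halved separately.
#'
#' @param corpus a `nursing_corpus` with at least 2 patients.
#' @param fraction proportion of patients in the first part, in (0, 1).
#' @param seed integer seed; the split is deterministic given the seed.
#' @param stratify split within class strata (default `TRUE`).
#' @return list with corpora `part1` and `part2`.
#' @export
split_patients <- function(corpus, fraction = 0.5, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(corpus, "nursing_corpus"))
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  ids <- corpus$patients$patient_id
  if (length(ids) < 2L) stop("need at least 2 patients to split")
  first <- with_seed(seed, {
    if (stratify) {
      unlist(lapply(split(ids, corpus$patients$label), function(g) {
        sample(g, floor(fraction * length(g)))
      }), use.names = FALSE)
    } else {
      sample(ids, floor(fraction * length(ids)))
    }
  })
  second <- setdiff(ids, first)
  list(part1 = subset_corpus(corpus, first,
                             sprintf("split part1 (seed %d)", seed)),
       part2 = subset_corpus(corpus, second,
                             sprintf("split part2 (seed %d)", seed)))
}
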
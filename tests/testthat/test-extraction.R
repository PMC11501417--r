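cfg <- default_rule_config()
tiny_idx <- build_surface_index(tiny_lexicon(), "en")

test_that("clause segmentation partitions text into punctuation-free spans", {
  expect_equal(nrow(segment_clauses("A; B.", cfg)), 2)
  expect_equal(nrow(segment_clauses("no punctuation at all", cfg)), 1)
  expect_equal(nrow(segment_clauses("   ", cfg)), 0)

  set.seed(101)
  words <- c("alpha", "beta", "gamma", "but", "then", "x2")
  seps <- c(". ", "; ", ", ", "? ")
  for (rep in 1:20) {
    text <- paste0(
      paste(sample(words, sample(3:12, 1), replace = TRUE), collapse = " "),
      sample(seps, 1),
      paste(sample(words, sample(1:8, 1), replace = TRUE), collapse = " "))
    cl <- segment_clauses(text, cfg)
    # raw slice at each span equals the clause; spans don't overlap
    for (i in seq_len(nrow(cl))) {
      expect_identical(substr(text, cl$start[i] + 1, cl$end[i]), cl$clause[i])
    }
    expect_true(all(diff(cl$start) > 0))
    expect_true(all(cl$start[-1] >= cl$end[-nrow(cl)]))
    # complement of the clause spans is only separators and whitespace
    covered <- logical(nchar(text))
    for (i in seq_len(nrow(cl)))
      covered[(cl$start[i] + 1):cl$end[i]] <- TRUE
    left <- strsplit(text, "")[[1]][!covered]
    expect_true(all(left %in% c(strsplit(".;!?,:", "")[[1]], " ")))
  }
})

test_that("matching is leftmost-longest: whole phrases beat their parts", {
  m <- match_terms("tonic clonic seizure", tiny_idx)
  expect_equal(nrow(m), 1)
  expect_equal(m$surface, "tonic clonic")
  expect_equal(m$term_id, "T1")

  expect_equal(nrow(match_terms("nothing relevant here", tiny_idx)), 0)

  # synonym hits report the owning term; raw slice preserved with offsets
  m <- match_terms("sudden Jerking of the left arm", tiny_idx, offset = 10L)
  expect_equal(m$term_id, c("T3", "T5"))
  expect_equal(m$surface[1], "Jerking")
  expect_equal(m$start[1] - 10L, 7L)

  # no matches inside longer words
  expect_equal(nrow(match_terms("catatonic state", tiny_idx)), 0)
})

test_that("greedy matching equals brute-force enumeration on random clauses", {
  set.seed(202)
  entries <- tiny_idx$entries
  frags <- c(entries$surface, "sei", "zure", "ton", "arm", "x", "of the")
  for (rep in 1:60) {
    clause <- paste(sample(frags, sample(1:6, 1), replace = TRUE),
                    collapse = " ")
    clause <- substr(clause, 1, 40)
    got <- match_terms(clause, tiny_idx)
    want <- bf_leftmost_longest(clause, entries)
    expect_equal(nrow(got), nrow(want), info = clause)
    if (nrow(want)) {
      expect_equal(got$start, want$start, info = clause)
      expect_equal(got$term_id, want$term_id, info = clause)
    }
  }
})

test_that("status assignment honors negation, defaults, and scope breaks", {
  lx <- default_semiology_lexicon()
  idx <- build_surface_index(lx, "en")
  status_of <- function(clause, surface) {
    m <- match_terms(clause, idx)
    m <- m[normalize_surface(m$surface) == surface, , drop = FALSE]
    assign_status(m[1, ], clause, cfg)
  }
  expect_equal(status_of("without loss of consciousness",
                         "loss of consciousness"), "without")
  expect_equal(status_of("loss of consciousness", "loss of consciousness"),
               "with")
  expect_equal(status_of("he denied tongue biting", "tongue biting"),
               "without")
  expect_equal(status_of("possibly staring", "staring"), "unknown")
  # a connective between cue and mention breaks the negation scope
  clause <- "no tonic stiffening but clonic jerking"
  expect_equal(status_of(clause, "tonic stiffening"), "without")
  expect_equal(status_of(clause, "clonic jerking"), "with")
  # cue outside the token window does not negate
  far <- paste("no sign was seen back then and later on came",
               "clonic jerking")
  expect_equal(status_of(far, "clonic jerking"), "with")
})

test_that("durations normalize via the unit table, ranges to midpoints", {
  expect_equal(parse_duration("lasting 2 minutes", cfg)$seconds, 120)
  expect_equal(parse_duration("episodes of 45 seconds", cfg)$seconds, 45)
  expect_equal(parse_duration("1-2 minutes", cfg)$seconds, 90)
  expect_equal(parse_duration("lasting 1 to 3 hours", cfg)$seconds, 7200)
  expect_equal(parse_duration("lasting 2 minutes", cfg)$raw, "2 minutes")
  expect_null(parse_duration("for a while", cfg))
  expect_null(parse_duration("", cfg))
})

test_that("frequencies normalize to per-day under day/month/year conventions", {
  expect_equal(parse_frequency("once a month", cfg)$per_day, 1 / 30)
  expect_equal(parse_frequency("3 times per day", cfg)$per_day, 3)
  expect_equal(parse_frequency("twice a year", cfg)$per_day, 2 / 365)
  expect_equal(parse_frequency("once every 2 weeks", cfg)$per_day, 1 / 14)
  expect_null(parse_frequency("frequently", cfg))
})

test_that("temporal anchors are found in order, with an onset fallback", {
  ts <- detect_timestamps(
    "3 years ago he fell. 2 months ago it worsened.", cfg)
  expect_equal(ts$anchor, c("3 years ago", "2 months ago"))
  expect_true(all(diff(ts$offset) > 0))

  ts <- detect_timestamps("no temporal cue in this text", cfg)
  expect_equal(ts$anchor, "onset")
  expect_equal(ts$offset, 0L)

  # anchor offsets strictly increase for generated texts
  set.seed(303)
  pool <- c("5 years ago", "8 months ago", "2 weeks ago", "filler words",
            "more filler")
  for (rep in 1:10) {
    text <- paste(sample(pool, 4, replace = TRUE), collapse = ". ")
    ts <- detect_timestamps(text, cfg)
    expect_true(all(diff(ts$offset) > 0))
  }
})

test_that("document extraction fills all six framework slots and is deterministic", {
  lx <- default_semiology_lexicon()
  rules <- default_rule_config(lx)
  # a note exercising every slot: time stamp, symptom, location, status,
  # episode duration, frequency
  text <- paste("2 years ago, the patient developed clonic jerking",
                "involving the left arm, lasting 2 minutes, about once a",
                "month. There was no staring.")
  doc <- list(doc_id = "d1", text = text)
  recs <- extract_document(doc, lx, rules)
  expect_length(recs, 1)
  r <- recs[[1]]
  expect_equal(r$time_stamp, "2 years ago")
  expect_equal(r$symptoms$term_id, c("ESO:S001", "ESO:S012"))
  expect_equal(r$symptoms$status, c("with", "without"))
  expect_equal(r$locations$term_id, "ESO:L001")
  expect_equal(r$episode_time$seconds, 120)
  expect_equal(r$frequency$per_day, 1 / 30)
  # raw text slice at each span equals the mention surface
  for (i in seq_len(nrow(r$symptoms)))
    expect_identical(substr(text, r$symptoms$start[i] + 1, r$symptoms$end[i]),
                     r$symptoms$surface[i])

  # single affirmed symptom, no temporal cue: one onset record
  recs <- extract_document(list(doc_id = "d2", text = "he had staring"),
                           lx, rules)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$time_stamp, "onset")
  expect_equal(recs[[1]]$symptoms$status, "with")

  expect_length(extract_document(list(doc_id = "d3", text = "  "), lx, rules),
                0)

  # determinism: identical inputs give identical records
  r1 <- extract_document(doc, lx, rules)
  r2 <- extract_document(doc, lx, rules)
  expect_identical(r1, r2)
})

test_that("extracted mentions always reference lexicon terms", {
  lx <- default_semiology_lexicon()
  rules <- default_rule_config(lx)
  b <- generate_cohort(cohort_spec(n_docs = 20, seed = 99))
  recs <- extract_corpus(b$documents, lx, rules)
  ids <- unlist(lapply(recs, function(r)
    c(r$symptoms$term_id, r$locations$term_id)))
  expect_true(all(ids %in% names(lx$terms)))
})

test_that("records survive a JSON-Lines round trip", {
  lx <- default_semiology_lexicon()
  rules <- default_rule_config(lx)
  b <- generate_cohort(cohort_spec(n_docs = 8, seed = 5))
  recs <- extract_corpus(b$documents, lx, rules)
  path <- tmpf(".jsonl")
  write_records(recs, path)
  back <- read_records(path)
  expect_equal(back, recs, tolerance = 1e-12)
})
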
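# small record builders for alignment tests
rec <- function(doc, anchor, syms = NULL, locs = NULL, dur = NULL,
                freq = NULL) {
  mk <- function(df, cat) {
    if (is.null(df)) return(NULL)
    data.frame(surface = df$term, start = 0L, end = 1L, term_id = df$term,
               category = cat, status = df$status, stringsAsFactors = FALSE)
  }
  r <- list(doc_id = doc, time_stamp = anchor,
            symptoms = mk(syms, "symptom"), locations = mk(locs, "location"),
            episode_time = if (is.null(dur)) NULL else
              list(raw = "d", seconds = dur),
            frequency = if (is.null(freq)) NULL else
              list(raw = "f", per_day = freq))
  if (is.null(r$symptoms))
    r$symptoms <- data.frame(surface = character(0), start = integer(0),
                             end = integer(0), term_id = character(0),
                             category = character(0), status = character(0))
  if (is.null(r$locations)) r$locations <- r$symptoms[0, ]
  class(r) <- "episemio_record"
  r
}
sy <- function(...) {
  terms <- c(...)
  data.frame(term = terms, status = rep_len("with", length(terms)),
             stringsAsFactors = FALSE)
}

test_that("alignment counts gold, reported and correct elements", {
  g <- list(rec("d1", "onset", sy("A", "B")))
  # identical records: everything correct
  ct <- align_elements(g, g, "symptom")
  expect_equal(ct$gold_total, 2); expect_equal(ct$reported_total, 2)
  expect_equal(ct$correct, 2)
  # one spurious extra prediction
  p <- list(rec("d1", "onset", sy("A", "B", "C")))
  ct <- align_elements(g, p, "symptom")
  expect_equal(ct$correct, 2); expect_equal(ct$reported_total, 3)
  # duplicate gold elements are not double-credited by one prediction
  g2 <- list(rec("d1", "onset", sy("A", "A")))
  p2 <- list(rec("d1", "onset", sy("A")))
  expect_equal(align_elements(g2, p2, "symptom")$correct, 1)
  # elements in different records do not match across anchors
  g3 <- list(rec("d1", "1 year ago", sy("A")), rec("d1", "onset", sy("B")))
  p3 <- list(rec("d1", "1 year ago", sy("B")), rec("d1", "onset", sy("A")))
  expect_equal(align_elements(g3, p3, "symptom")$correct, 0)
  # status dimension requires the status value to agree
  gs <- list(rec("d1", "onset",
                 data.frame(term = "A", status = "with")))
  ps <- list(rec("d1", "onset",
                 data.frame(term = "A", status = "without")))
  expect_equal(align_elements(gs, ps, "symptom")$correct, 1)
  expect_equal(align_elements(gs, ps, "status")$correct, 0)
  expect_error(align_elements(g, g, "nonsense"), "dimension")
})

test_that("alignment equals brute-force maximum bipartite matching", {
  set.seed(77)
  pool <- c("A", "B", "C", "D")
  for (rep in 1:40) {
    ge <- sample(pool, sample(0:6, 1), replace = TRUE)
    pe <- sample(pool, sample(0:6, 1), replace = TRUE)
    g <- list(rec("d1", "onset", if (length(ge)) sy(ge) else NULL))
    p <- list(rec("d1", "onset", if (length(pe)) sy(pe) else NULL))
    expect_equal(align_elements(g, p, "symptom")$correct,
                 bf_max_matching(ge, pe))
  }
})

test_that("swapping gold and prediction swaps precision and recall", {
  g <- list(rec("d1", "onset", sy("A", "B", "C")),
            rec("d2", "onset", sy("A")))
  p <- list(rec("d1", "onset", sy("A", "B", "D", "D")),
            rec("d2", "onset", sy("B")))
  m1 <- suppressWarnings(prf(align_elements(g, p, "symptom")))
  m2 <- suppressWarnings(prf(align_elements(p, g, "symptom")))
  expect_equal(m1$precision, m2$recall)
  expect_equal(m1$recall, m2$precision)
  expect_equal(m1$f1, m2$f1)
})

test_that("metric arithmetic reproduces published per-dimension cells", {
  # symptom column: 1126 correct of 1325 gold / 1219 reported
  m <- prf(eval_counts("symptom", 1325, 1219, 1126))
  t <- prf_table(eval_counts("symptom", 1325, 1219, 1126))
  expect_equal(t$recall_pct, 85)
  expect_equal(t$precision_pct, 92)
  expect_equal(t$f1, 0.88)
  expect_equal(round(m$recall, 2), 0.85)
  expect_equal(round(m$precision, 2), 0.92)
  # frequency column: 84 of 106 / 93
  t <- prf_table(eval_counts("frequency", 106, 93, 84))
  expect_equal(t$recall_pct, 79)
  expect_equal(t$precision_pct, 90)
  expect_equal(t$f1, 0.84)
  # nothing correct
  m <- prf(eval_counts("symptom", 10, 5, 0))
  expect_equal(c(m$recall, m$precision, m$f1), c(0, 0, 0))
  expect_warning(prf(eval_counts("symptom", 0, 0, 0)), "metrics")
})

test_that("prf is monotone in correct and f1 lies between P and R", {
  for (correct in 0:8) {
    m <- prf(eval_counts("symptom", 10, 8, correct))
    expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    if (correct > 0) {
      prev <- prf(eval_counts("symptom", 10, 8, correct - 1))
      expect_gte(m$recall, prev$recall)
      expect_gte(m$precision, prev$precision)
      expect_gte(m$f1, prev$f1)
    }
  }
  m <- prf(eval_counts("symptom", 10, 10, 7))  # P = R implies F1 = P
  expect_equal(m$f1, m$precision)
})

test_that("Fleiss's kappa matches hand and brute-force evaluation", {
  # perfect agreement over >= 2 used categories
  perfect <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(fleiss_kappa(perfect), 1.0)
  # 3 items, 2 raters: Pbar = 2/3, Pe = 1/2, kappa = 1/3
  R <- rbind(c(2, 0), c(0, 2), c(1, 1))
  expect_equal(fleiss_kappa(R), 1 / 3)
  expect_equal(fleiss_kappa(R), bf_fleiss(R))
  # brute-force equivalence on random small matrices (<= 5 x 3)
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(2:5, 1); k <- sample(2:3, 1); m <- sample(2:4, 1)
    Rm <- t(replicate(n, as.integer(stats::rmultinom(1, m, runif(k)))))
    if (sum(colSums(Rm) > 0) < 2) next
    expect_equal(fleiss_kappa(Rm), bf_fleiss(Rm), tolerance = 1e-12)
  }
  # invariance to permuting items and categories
  Rm <- rbind(c(2, 1, 1), c(0, 3, 1), c(4, 0, 0), c(1, 1, 2))
  expect_equal(fleiss_kappa(Rm[sample(4), ]), fleiss_kappa(Rm))
  expect_equal(fleiss_kappa(Rm[, c(3, 1, 2)]), fleiss_kappa(Rm))
  # random ratings agree at chance level
  set.seed(12)
  big <- t(replicate(4000, as.integer(stats::rmultinom(1, 3, c(1, 1, 1)))))
  expect_lt(abs(fleiss_kappa(big)), 0.02)
  # errors: ragged rows, single used category
  expect_error(fleiss_kappa(rbind(c(2, 0), c(1, 0))), "same number")
  expect_error(fleiss_kappa(rbind(c(2, 0), c(2, 0))), "single category")
})

test_that("review sampling is uniform, seed-stable, and bounded", {
  x <- as.list(letters[1:8])
  expect_setequal(unlist(sample_for_review(x, 8, seed = 1)), letters[1:8])
  expect_identical(sample_for_review(x, 3, seed = 42),
                   sample_for_review(x, 3, seed = 42))
  expect_error(sample_for_review(x, 9, seed = 1), "cannot sample")
  # inclusion frequency ~ n/N over many replicates
  counts <- integer(8); names(counts) <- letters[1:8]
  for (s in 1:4000) {
    got <- unlist(sample_for_review(x, 2, seed = s))
    counts[got] <- counts[got] + 1L
  }
  expect_true(all(abs(counts / 4000 - 0.25) < 0.03))
})
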
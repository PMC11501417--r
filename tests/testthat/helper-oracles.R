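# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results by enumeration so they
# share no code path with the implementation they check.

# tiny lexicon with nested phrases, for matcher tests
tiny_lexicon <- function() {
  lexicon(list(
    term("T1", c(en = "tonic clonic"), list(), "symptom"),
    term("T2", c(en = "tonic"), list(), "symptom"),
    term("T3", c(en = "clonic"), list(en = "jerking"), "symptom"),
    term("T4", c(en = "staring"), list(), "symptom"),
    term("T5", c(en = "left arm"), list(), "location")
  ), name = "tiny", languages = "en")
}

# leftmost-longest greedy matching by exhaustive enumeration + interval
# scheduling: list every (start, surface) occurrence honoring the word
# boundary rule, then repeatedly keep the earliest (longest on ties)
# non-overlapping match.
bf_leftmost_longest <- function(clause, entries) {
  norm <- tolower(clause)
  occ <- list()
  for (i in seq_len(nrow(entries))) {
    s <- entries$surface[i]
    L <- nchar(s)
    if (L == 0 || L > nchar(norm)) next
    for (pos in seq_len(nchar(norm) - L + 1)) {
      if (substr(norm, pos, pos + L - 1) != s) next
      pre <- if (pos > 1) substr(norm, pos - 1, pos - 1) else ""
      post <- if (pos + L <= nchar(norm)) substr(norm, pos + L, pos + L) else ""
      edge1 <- substr(s, 1, 1); edge2 <- substr(s, L, L)
      if (grepl("[a-z0-9]", edge1) && grepl("[a-z0-9]", pre)) next
      if (grepl("[a-z0-9]", edge2) && grepl("[a-z0-9]", post)) next
      occ[[length(occ) + 1L]] <- data.frame(
        start = pos - 1L, len = L, term_id = entries$term_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(occ)) return(data.frame(start = integer(0), len = integer(0),
                                      term_id = character(0)))
  occ <- do.call(rbind, occ)
  kept <- list()
  cursor <- 0L
  repeat {
    cand <- occ[occ$start >= cursor, , drop = FALSE]
    if (!nrow(cand)) break
    cand <- cand[order(cand$start, -cand$len), , drop = FALSE]
    kept[[length(kept) + 1L]] <- cand[1, ]
    cursor <- cand$start[1] + cand$len[1]
  }
  do.call(rbind, c(kept, list(make.row.names = FALSE)))
}

# maximum one-to-one matching between two element vectors under equality
# edges, by exhaustive recursion (instances <= ~6 per side)
bf_max_matching <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  best <- 0L
  recurse <- function(i, used, size) {
    if (size + (length(a) - i + 1L) <= best) return()
    if (i > length(a)) { best <<- max(best, size); return() }
    for (j in seq_along(b)) {
      if (!used[j] && a[i] == b[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, size + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, size)
  }
  recurse(1L, logical(length(b)), 0L)
  best
}

# Fleiss's kappa by direct pairwise-agreement counting over rater pairs
bf_fleiss <- function(ratings) {
  n <- nrow(ratings); m <- sum(ratings[1, ])
  agree <- vapply(seq_len(n), function(i) {
    pairs <- sum(choose(ratings[i, ], 2))
    pairs / choose(m, 2)
  }, numeric(1))
  p_j <- colSums(ratings) / (n * m)
  (mean(agree) - sum(p_j^2)) / (1 - sum(p_j^2))
}

# independent per-class metric recomputation from raw label vectors
bf_macro <- function(pred, y) {
  per_class <- function(cls) {
    tp <- sum(pred == cls & y == cls)
    fp <- sum(pred == cls & y != cls)
    fn <- sum(pred != cls & y == cls)
    c(p = if (tp + fp > 0) tp / (tp + fp) else 0,
      r = if (tp + fn > 0) tp / (tp + fn) else 0)
  }
  a <- per_class("generalized"); b <- per_class("focal")
  p <- mean(c(a["p"], b["p"])); r <- mean(c(a["r"], b["r"]))
  list(precision = p, recall = r,
       f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# random lexicon generator for round-trip properties
random_lexicon <- function(n_terms, seed) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    terms <- lapply(seq_len(n_terms), function(i) {
      cat_i <- sample(c("symptom", "location"), 1)
      n_syn <- sample(0:3, 1)
      base <- sprintf("w%03dx", i)
      term(sprintf("T%03d", i), c(en = base),
           if (n_syn) list(en = sprintf("%s syn%d", base, seq_len(n_syn)))
           else list(),
           cat_i,
           parent = if (i > 1 && runif(1) < 0.3)
             sprintf("T%03d", sample(i - 1, 1)) else NULL)
    })
    lexicon(terms, name = "random", version = "9.9", languages = "en")
  })
}

tmpf <- function(ext = ".json") tempfile(fileext = ext)
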
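# Scoring extraction output against gold annotations, per dimension, plus
# Fleiss's kappa for inter-annotator agreement.

EVAL_DIMENSIONS <- c("time_stamp", "location", "symptom", "episode_time",
                     "status", "frequency")

# Elements of one record along one evaluation dimension. `term` mode
# compares concept identity (term ids; status pairs concept with its
# occurrence state); `exact_text` compares normalized surfaces.
record_elements <- function(r, dimension, mode = "term") {
  switch(dimension,
    time_stamp = normalize_surface(r$time_stamp),
    symptom = if (mode == "term") r$symptoms$term_id
              else normalize_surface(r$symptoms$surface),
    location = if (mode == "term") r$locations$term_id
               else normalize_surface(r$locations$surface),
    status = if (mode == "term")
               paste(r$symptoms$term_id, r$symptoms$status, sep = "\r")
             else paste(normalize_surface(r$symptoms$surface),
                        r$symptoms$status, sep = "\r"),
    episode_time = if (is.null(r$episode_time)) character(0)
                   else as.character(r$episode_time$seconds),
    frequency = if (is.null(r$frequency)) character(0)
                else as.character(signif(r$frequency$per_day, 12)),
    stop("unknown dimension: ", dimension)
  )
}

# size of the maximum one-to-one matching between two element multisets
# under equality edges = multiset intersection size
multiset_intersection <- function(a, b) {
  if (!length(a) || !length(b)) return(0L)
  ta <- table(a); tb <- table(b)
  common <- intersect(names(ta), names(tb))
  sum(pmin(as.integer(ta[common]), as.integer(tb[common])))
}

#' Align gold and predicted records along one dimension
#'
#' Counts, for one evaluation dimension, how many gold elements the
#' extractor reported correctly. Records are grouped by document and paired
#' by time stamp (in order); within each paired record the number of
#' correct elements is the size of a maximum one-to-one matching between
#' gold and predicted element multisets — for equality-based matching this
#' equals the multiset intersection. In `term` mode elements are concept
#' identities (term ids; for the `status` dimension, term id plus status
#' value); `exact_text` mode compares normalized surface strings, for
#' stricter audits. For the `time_stamp` dimension the anchors of a
#' document are themselves the elements.
#'
#' @param gold,pred Lists of `episemio_record`.
#' @param dimension One of `time_stamp`, `location`, `symptom`,
#'   `episode_time`, `status`, `frequency`.
#' @param mode `"term"` (default) or `"exact_text"`.
#' @return An `episemio_eval_counts` list: `dimension`, `gold_total`,
#'   `reported_total`, `correct`.
#' @export
align_elements <- function(gold, pred, dimension, mode = c("term", "exact_text")) {
  mode <- match.arg(mode)
  if (!dimension %in% EVAL_DIMENSIONS)
    stop("unknown dimension: ", dimension)
  gold_by_doc <- split(gold, vapply(gold, `[[`, character(1), "doc_id"))
  pred_by_doc <- split(pred, vapply(pred, `[[`, character(1), "doc_id"))
  gold_total <- 0L; reported_total <- 0L; correct <- 0L
  docs <- union(names(gold_by_doc), names(pred_by_doc))
  for (d in docs) {
    g <- gold_by_doc[[d]]; p <- pred_by_doc[[d]]
    if (is.null(g)) g <- list()
    if (is.null(p)) p <- list()
    if (dimension == "time_stamp") {
      ge <- unlist(lapply(g, record_elements, "time_stamp"))
      pe <- unlist(lapply(p, record_elements, "time_stamp"))
      gold_total <- gold_total + length(ge)
      reported_total <- reported_total + length(pe)
      correct <- correct + multiset_intersection(ge, pe)
      next
    }
    # pair records by anchor string, in order; leftovers stay unpaired
    ganch <- vapply(g, function(r) normalize_surface(r$time_stamp), character(1))
    panch <- vapply(p, function(r) normalize_surface(r$time_stamp), character(1))
    used <- logical(length(p))
    for (i in seq_along(g)) {
      ge <- record_elements(g[[i]], dimension, mode)
      gold_total <- gold_total + length(ge)
      j <- which(!used & panch == ganch[i])
      if (length(j)) {
        j <- j[1]
        used[j] <- TRUE
        pe <- record_elements(p[[j]], dimension, mode)
        correct <- correct + multiset_intersection(ge, pe)
      }
    }
    for (j in seq_along(p)) {
      reported_total <- reported_total +
        length(record_elements(p[[j]], dimension, mode))
    }
  }
  eval_counts(dimension, gold_total, reported_total, correct)
}

#' Construct per-dimension evaluation counts
#'
#' @param dimension Dimension name.
#' @param gold_total Elements in the gold standard.
#' @param reported_total Elements reported by the extractor.
#' @param correct Correctly reported elements; cannot exceed either total.
#' @return An `episemio_eval_counts` list.
#' @export
eval_counts <- function(dimension, gold_total, reported_total, correct) {
  gold_total <- as.integer(gold_total)
  reported_total <- as.integer(reported_total)
  correct <- as.integer(correct)
  stopifnot(gold_total >= 0L, reported_total >= 0L, correct >= 0L,
            correct <= min(gold_total, reported_total) ||
              (gold_total == 0L && reported_total == 0L && correct == 0L))
  structure(list(dimension = dimension, gold_total = gold_total,
                 reported_total = reported_total, correct = correct),
            class = "episemio_eval_counts")
}

#' Precision, recall and F1 from evaluation counts
#'
#' `recall = correct / gold_total`, `precision = correct / reported_total`,
#' `f1 = 2PR/(P+R)`; any 0/0 is defined as 0 with a warning and the
#' `degenerate` flag set.
#'
#' @param counts An `episemio_eval_counts` (or a list with `gold_total`,
#'   `reported_total`, `correct`).
#' @return List with `recall`, `precision`, `f1` (unrounded fractions) and
#'   `degenerate`.
#' @seealso [prf_table()] for the printed-table convention.
#' @export
#' @examples
#' m <- prf(eval_counts("symptom", 1325, 1219, 1126))
#' round(100 * m$recall)   # 85
prf <- function(counts) {
  g <- counts$gold_total; r <- counts$reported_total; k <- counts$correct
  degenerate <- FALSE
  if (g == 0 && r == 0) {
    warning("no gold and no reported elements; metrics defined as 0")
    return(list(recall = 0, precision = 0, f1 = 0, degenerate = TRUE))
  }
  if (g == 0 || r == 0) degenerate <- TRUE
  recall <- if (g > 0) k / g else { warning("gold_total is 0; recall = 0"); 0 }
  precision <- if (r > 0) k / r else {
    warning("reported_total is 0; precision = 0"); 0 }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(recall = recall, precision = precision, f1 = f1, degenerate = degenerate)
}

#' Metrics in the printed-table convention
#'
#' Reproduces the arithmetic used when a performance table is typeset:
#' recall and precision are shown as whole percentages (rounded half-up)
#' and the F1 score is computed from precision and recall rounded to two
#' decimals first, then itself rounded half-up to two decimals. Computing
#' F1 from unrounded P and R can differ from such a printed cell by one
#' unit in the last digit, which is why both paths are exposed.
#'
#' @inheritParams prf
#' @return List with `recall_pct`, `precision_pct` (integers) and `f1`
#'   (two decimals).
#' @export
prf_table <- function(counts) {
  m <- prf(counts)
  p2 <- round_half_up(m$precision, 2)
  r2 <- round_half_up(m$recall, 2)
  f1 <- if (p2 + r2 > 0) 2 * p2 * r2 / (p2 + r2) else 0
  list(recall_pct = round_half_up(100 * m$recall),
       precision_pct = round_half_up(100 * m$precision),
       f1 = round_half_up(f1, 2))
}

#' Score a corpus extraction against gold on all dimensions
#'
#' @param gold,pred Lists of `episemio_record`.
#' @param mode Matching mode, see [align_elements()].
#' @return Data frame with one row per dimension: counts, exact metrics,
#'   and table-convention metrics.
#' @export
evaluate_extraction <- function(gold, pred, mode = "term") {
  rows <- lapply(EVAL_DIMENSIONS, function(dim) {
    ct <- align_elements(gold, pred, dim, mode)
    m <- suppressWarnings(prf(ct))
    t <- suppressWarnings(prf_table(ct))
    data.frame(dimension = dim, gold_total = ct$gold_total,
               reported_total = ct$reported_total, correct = ct$correct,
               recall = m$recall, precision = m$precision, f1 = m$f1,
               recall_pct = t$recall_pct, precision_pct = t$precision_pct,
               f1_table = t$f1, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fleiss's kappa for multiple raters
#'
#' Chance-corrected agreement for `n` items rated by a constant number `m`
#' of raters into `k` categories: `kappa = (Pbar - Pe) / (1 - Pe)` where
#' `Pbar` is the mean observed pairwise agreement per item and `Pe` the
#' agreement expected from the marginal category proportions. A value above
#' 0.80 is conventionally read as near-perfect agreement.
#'
#' @param ratings Integer matrix, items x categories; cell (i, j) counts
#'   the raters assigning item i to category j. All row sums must equal the
#'   (constant) number of raters, at least 2.
#' @return Kappa (1 under perfect agreement across >= 2 used categories).
#' @export
#' @examples
#' fleiss_kappa(rbind(c(2, 0), c(0, 2), c(1, 1)))
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(ratings < 0) || any(ratings != round(ratings)))
    stop("ratings must be non-negative integer counts")
  m <- sum(ratings[1, ])
  if (m < 2) stop("need at least 2 raters per item")
  if (any(rowSums(ratings) != m))
    stop("all items must be rated by the same number of raters (", m, ")")
  n <- nrow(ratings)
  p_j <- colSums(ratings) / (n * m)
  P_i <- (rowSums(ratings^2) - m) / (m * (m - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (1 - Pe <= .Machine$double.eps)
    stop("expected agreement is 1 (a single category used); kappa undefined")
  (Pbar - Pe) / (1 - Pe)
}

#' Draw a reproducible review sample
#'
#' Uniform sampling without replacement, as used to pull a random subset of
#' extraction results for manual inspection. The caller's RNG state is left
#' untouched.
#'
#' @param records A list (or vector) to sample from.
#' @param n Sample size; must not exceed the population.
#' @param seed Integer seed making the draw reproducible.
#' @return The sampled subset, in draw order.
#' @export
sample_for_review <- function(records, n, seed) {
  if (n > length(records))
    stop("cannot sample ", n, " from ", length(records), " records")
  idx <- with_seed(seed, sample.int(length(records), n))
  records[idx]
}
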
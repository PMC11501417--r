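# Turning extracted records plus diagnosis strings into a labeled binary
# symptom feature matrix.

#' Default diagnosis-string mapping rules
#'
#' Ordered regular-expression rules mapping a free-text discharge diagnosis
#' to `generalized` or `focal`; the first matching rule wins and unmatched
#' strings map to `unclassified`. Generalized patterns come first so that
#' e.g. "generalized tonic-clonic epilepsy" is not captured by a focal
#' pattern.
#'
#' @return Data frame with columns `pattern` and `label`.
#' @export
default_diagnosis_rules <- function() {
  data.frame(
    pattern = c(
      "generali[sz]ed|absence|myoclon|tonic[- ]clonic epilep|grand mal",
      "focal|partial|temporal lobe|frontal lobe|occipital|parietal|rolandic"
    ),
    label = c("generalized", "focal"),
    stringsAsFactors = FALSE
  )
}

#' Map a diagnosis string to an epilepsy class
#'
#' @param diagnosis Character vector of diagnosis strings.
#' @param rules Ordered rule table (`pattern`, `label`); first match wins.
#'   Matching is case-insensitive on the normalized string.
#' @return Character vector in `{"generalized", "focal", "unclassified"}`.
#' @export
#' @examples
#' map_diagnosis(c("Generalized tonic-clonic epilepsy", "epilepsy, unspecified"))
map_diagnosis <- function(diagnosis, rules = default_diagnosis_rules()) {
  if (!is.data.frame(rules) || nrow(rules) == 0L)
    stop("rules must be a non-empty data frame with 'pattern' and 'label'")
  x <- normalize_surface(as.character(diagnosis))
  out <- rep("unclassified", length(x))
  undecided <- rep(TRUE, length(x))
  for (i in seq_len(nrow(rules))) {
    hit <- undecided & grepl(rules$pattern[i], x, perl = TRUE)
    out[hit] <- rules$label[i]
    undecided <- undecided & !hit
  }
  out[is.na(x)] <- "unclassified"
  out
}

#' Symptom vocabulary for the feature matrix
#'
#' The ordered list of canonical symptom term ids a cohort is encoded
#' against. By default it is built from a lexicon's symptom terms (in
#' stable id order), with the English label as the display label. The order
#' is part of the serialized matrix and must not change between encoding
#' and modeling.
#'
#' @param lx An `episemio_lexicon`.
#' @param language Language the display labels are taken from.
#' @return An `episemio_vocab`: data frame with `term_id`, `label`.
#' @export
symptom_vocabulary <- function(lx, language = "en") {
  stopifnot(inherits(lx, "episemio_lexicon"))
  ids <- names(lx$terms)[vapply(lx$terms, function(t)
    t$category == "symptom", logical(1))]
  ids <- sort(ids)
  labels <- vapply(ids, function(id) {
    lab <- lx$terms[[id]]$labels[[language]]
    if (is.null(lab)) id else lab
  }, character(1))
  structure(data.frame(term_id = ids, label = unname(labels),
                       stringsAsFactors = FALSE),
            class = c("episemio_vocab", "data.frame"))
}

#' Build the binary document-by-symptom feature matrix
#'
#' Encodes each labeled document as a binary vector over the symptom
#' vocabulary: entry (i, j) is 1 iff some record of document i contains a
#' symptom mention of vocabulary term j with status `"with"`. Explicitly
#' negated mentions (pertinent negatives, status `"without"`) and unknowns
#' encode as 0 — absence, not a third value. Documents whose label is not
#' `generalized`/`focal` must be excluded before calling. Symptom mentions
#' whose term is outside the vocabulary are ignored (their count is
#' reported via a message).
#'
#' @param records Flat list of `episemio_record` (any order; the encoding
#'   is invariant to record order within a document).
#' @param vocab An [symptom_vocabulary()] data frame.
#' @param labels Named character vector or data frame (`doc_id`, `label`)
#'   mapping each document to `generalized` or `focal`.
#' @return An `episemio_feature_matrix`: list with `doc_ids`, binary
#'   integer matrix `X` (docs x vocabulary, columns named by term id) and
#'   factor `y` with levels `generalized`, `focal`.
#' @export
build_feature_matrix <- function(records, vocab, labels) {
  stopifnot(inherits(vocab, "episemio_vocab"))
  if (is.data.frame(labels)) {
    col <- if (!is.null(labels$label)) labels$label else labels$class
    lab <- stats::setNames(as.character(col), labels$doc_id)
  } else {
    lab <- labels
  }
  bad <- !lab %in% c("generalized", "focal")
  if (any(bad))
    stop("labels must be 'generalized' or 'focal'; exclude unclassified ",
         "documents first (offending: ",
         paste(utils::head(names(lab)[bad], 3), collapse = ", "), ")")
  doc_ids <- names(lab)
  X <- matrix(0L, nrow = length(doc_ids), ncol = nrow(vocab),
              dimnames = list(doc_ids, vocab$term_id))
  skipped <- 0L
  for (r in records) {
    if (!r$doc_id %in% doc_ids) next
    s <- r$symptoms
    s <- s[s$status == "with", , drop = FALSE]
    for (tid in s$term_id) {
      if (tid %in% vocab$term_id) {
        X[r$doc_id, tid] <- 1L
      } else {
        skipped <- skipped + 1L
      }
    }
  }
  if (skipped > 0L)
    message(skipped, " symptom mention(s) outside the vocabulary ignored")
  structure(list(doc_ids = doc_ids, X = X,
                 y = factor(unname(lab), levels = c("generalized", "focal"))),
            class = "episemio_feature_matrix")
}

#' @export
print.episemio_feature_matrix <- function(x, ...) {
  cat("<episemio_feature_matrix> ", nrow(x$X), " docs x ", ncol(x$X),
      " symptom features; classes: ",
      paste(sprintf("%s=%d", levels(x$y), table(x$y)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

subset_fm <- function(fm, idx) {
  structure(list(doc_ids = fm$doc_ids[idx], X = fm$X[idx, , drop = FALSE],
                 y = fm$y[idx]), class = "episemio_feature_matrix")
}

#' Stratified train/test split
#'
#' Splits a feature matrix into train and test sets preserving the class
#' proportions. The train size is `round(ratio * n)`; per class,
#' `floor(ratio * n_class)` rows are drawn first and the remainder is
#' topped up from the classes with the largest fractional parts, so the
#' per-class counts differ from exact proportionality by at most one.
#'
#' @param fm An `episemio_feature_matrix`.
#' @param ratio Train fraction (default 0.7, i.e. a 7:3 split).
#' @param seed Integer seed; the same seed always yields the same split.
#' @param stratified Keep per-class proportions (default); otherwise a
#'   simple random split.
#' @return List with `train` and `test` feature matrices (disjoint, union
#'   = input).
#' @export
split_train_test <- function(fm, ratio = 0.7, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(fm, "episemio_feature_matrix"), ratio > 0, ratio < 1)
  n <- length(fm$y)
  tab <- table(fm$y)
  if (any(tab < 2L))
    stop("each class needs at least 2 members to split (got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")")
  n_train <- round_half_up(ratio * n)
  train_idx <- with_seed(seed, {
    if (!stratified) {
      sample.int(n, n_train)
    } else {
      base <- floor(ratio * as.integer(tab))
      frac <- ratio * as.integer(tab) - base
      topup <- n_train - sum(base)
      give <- rep(0L, length(tab))
      if (topup > 0L) {
        ord <- order(frac, decreasing = TRUE)
        give[ord[seq_len(topup)]] <- 1L
      }
      idx <- integer(0)
      for (k in seq_along(tab)) {
        members <- which(fm$y == names(tab)[k])
        idx <- c(idx, sample(members, base[k] + give[k]))
      }
      idx
    }
  })
  list(train = subset_fm(fm, sort(train_idx)),
       test = subset_fm(fm, sort(setdiff(seq_len(n), train_idx))))
}

#' Read and write the feature-matrix CSV
#'
#' Header `doc_id, <term ids...>, label`; labels serialized as
#' `generalized`/`focal`.
#'
#' @param fm An `episemio_feature_matrix`.
#' @param path CSV path.
#' @return `read_feature_matrix()` returns an `episemio_feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(doc_id = fm$doc_ids, fm$X, label = as.character(fm$y),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  feat <- setdiff(names(df), c("doc_id", "label"))
  X <- as.matrix(df[, feat, drop = FALSE])
  storage.mode(X) <- "integer"
  rownames(X) <- df$doc_id
  structure(list(doc_ids = df$doc_id, X = X,
                 y = factor(df$label, levels = c("generalized", "focal"))),
            class = "episemio_feature_matrix")
}
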
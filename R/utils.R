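# Internal helpers shared across modules.

#' Normalize a surface form for matching
#'
#' Applies the canonical surface normalization used everywhere a string is
#' compared against the lexicon: leading/trailing whitespace is trimmed,
#' Latin letters are case-folded, and full-width (CJK "zenkaku") ASCII
#' variants plus the ideographic space are mapped to their half-width
#' counterparts. Case- and width-folding are character-length preserving, so
#' the same transform can be applied to running text without invalidating
#' character offsets (see [match_terms()]).
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_surface(c(" Clonic ", "Ｔonic"))
normalize_surface <- function(x) {
  stopifnot(is.character(x))
  trimws(tolower(fold_width(x)))
}

# Width-fold only (no trim/case): used on running text where offsets matter.
fold_chars <- function(x) tolower(fold_width(x))

fold_width <- function(x) {
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(s)
    ints <- utf8ToInt(s)
    full <- ints >= 0xFF01L & ints <= 0xFF5EL
    ints[full] <- ints[full] - 0xFEE0L
    ints[ints == 0x3000L] <- 0x20L
    intToUtf8(ints)
  }, character(1), USE.NAMES = FALSE)
}

# Escape regex metacharacters for literal matching in a PCRE pattern.
regex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x, perl = TRUE)

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# nchar() on raw character counts, NA-safe.
nchr <- function(x) nchar(x, type = "chars")

#' Read and write JSON-Lines documents
#'
#' Documents are exchanged as JSON-Lines: one JSON object per line with at
#' least `doc_id` and `text` fields, optionally `diagnosis` and `lang`.
#'
#' @param path File path.
#' @param docs Data frame with columns `doc_id`, `text` and optionally
#'   `diagnosis`, `lang`.
#' @return `read_documents()` returns a data frame with one row per document.
#' @export
read_documents <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  out <- data.frame(
    doc_id = vapply(objs, function(o) as.character(o$doc_id), character(1)),
    text = vapply(objs, function(o) as.character(o$text), character(1)),
    stringsAsFactors = FALSE
  )
  if (any(vapply(objs, function(o) !is.null(o$diagnosis), logical(1)))) {
    out$diagnosis <- vapply(objs, function(o) {
      if (is.null(o$diagnosis)) NA_character_ else as.character(o$diagnosis)
    }, character(1))
  }
  out
}

#' @rdname read_documents
#' @export
write_documents <- function(docs, path) {
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(docs))) {
    obj <- as.list(docs[i, , drop = FALSE])
    obj <- obj[!vapply(obj, function(v) is.na(v[[1]]), logical(1))]
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
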
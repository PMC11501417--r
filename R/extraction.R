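# Rule-based extraction engine: clause segmentation, dictionary matching,
# negation/uncertainty scoping, temporal normalization, record assembly.

#' Rule configuration for the extraction engine
#'
#' Bundles the cue lists and pattern tables that drive extraction: negation,
#' uncertainty and connective cues, temporal-adverb anchors, and the
#' duration / frequency / time-stamp patterns. Cue scoping replaces
#' dependency parsing: a negation (or uncertainty) cue negates a mention
#' when it occurs within `scope_window` tokens before it (for unsegmented
#' CJK text, within `scope_window_chars` characters) with no intervening
#' connective or clause boundary. The scope resolver is deliberately the
#' only place this decision is made, so a parser-backed resolver can be
#' substituted without touching the rest of the pipeline.
#'
#' @param lexicon Optional `episemio_lexicon`; its `negation_cue`,
#'   `connective` and `temporal_adverb` surfaces are merged into the
#'   built-in lists.
#' @param language Language code the cue lists target.
#' @param scope_window Maximum tokens a cue may precede a mention by.
#' @param scope_window_chars Character window used when text has no token
#'   boundaries (CJK).
#' @return An object of class `episemio_rule_config`.
#' @export
default_rule_config <- function(lexicon = NULL, language = "en",
                                scope_window = 6L, scope_window_chars = 10L) {
  cfg <- list(
    language = language,
    negation_cues = c("no", "not", "without", "denies", "denied", "never had",
                      "absence of"),
    uncertainty_cues = c("possibly", "possible", "unclear whether",
                         "uncertain", "may have", "suspected", "questionable"),
    connectives = c("but", "however", "although", "whereas", "then",
                    "followed by", "except"),
    temporal_adverbs = c("initially", "subsequently", "thereafter"),
    timestamp_patterns = c(
      paste0("(?:\\d+(?:\\.\\d+)?|one|two|three|four|five|six|seven|eight|",
             "nine|ten|eleven|twelve|half a)\\s+(?:days?|weeks?|months?|years?)",
             "\\s+(?:ago|before admission|prior to admission)"),
      "at (?:disease )?onset",
      "since (?:childhood|infancy|birth)",
      "in (?:19|20)\\d{2}"
    ),
    duration_pattern = paste0(
      "(\\d+(?:\\.\\d+)?)(?:\\s*(?:-|–|~|to)\\s*(\\d+(?:\\.\\d+)?))?",
      "\\s*(seconds?|secs?|minutes?|mins?|hours?|hrs?)\\b"),
    duration_units = c(second = 1, sec = 1, minute = 60, min = 60,
                       hour = 3600, hr = 3600),
    frequency_pattern = paste0(
      "(once|twice|thrice|\\d+(?:\\.\\d+)?\\s*times?)",
      "\\s+(?:a|per|every)\\s+(day|week|month|year)s?\\b"),
    frequency_every_pattern =
      "(?:once\\s+)?every\\s+(\\d+(?:\\.\\d+)?)\\s+(days?|weeks?|months?|years?)\\b",
    frequency_unit_days = c(day = 1, week = 7, month = 30, year = 365),
    scope_direction = "pre",
    scope_window = as.integer(scope_window),
    scope_window_chars = as.integer(scope_window_chars),
    clause_separators = ".;!?,:。；！？，、："
  )
  if (!is.null(lexicon)) {
    stopifnot(inherits(lexicon, "episemio_lexicon"))
    if (language %in% lexicon$metadata$languages) {
      surf <- surface_table(lexicon, language)
      add <- function(cur, cat)
        unique(c(cur, surf$surface[surf$category == cat]))
      cfg$negation_cues <- add(cfg$negation_cues, "negation_cue")
      cfg$connectives <- add(cfg$connectives, "connective")
      cfg$temporal_adverbs <- add(cfg$temporal_adverbs, "temporal_adverb")
    }
  }
  cfg$negation_cues <- normalize_surface(cfg$negation_cues)
  cfg$uncertainty_cues <- normalize_surface(cfg$uncertainty_cues)
  cfg$connectives <- normalize_surface(cfg$connectives)
  cfg$temporal_adverbs <- normalize_surface(cfg$temporal_adverbs)
  structure(cfg, class = "episemio_rule_config")
}

empty_mentions <- function() {
  data.frame(surface = character(0), start = integer(0), end = integer(0),
             term_id = character(0), category = character(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Segment a narrative into clauses
#'
#' Splits text at sentence/clause punctuation and before logical
#' connectives. Clause spans are 0-based half-open character offsets into
#' the raw text; the clauses never overlap, the raw slice at each span
#' equals the clause string, and everything not covered by a clause is
#' separator punctuation or whitespace.
#'
#' @param text Narrative text.
#' @param cfg An `episemio_rule_config`.
#' @return Data frame with columns `clause`, `start`, `end`. Whitespace-only
#'   text yields zero rows.
#' @export
segment_clauses <- function(text, cfg = default_rule_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) {
    return(data.frame(clause = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "")[[1]]
  sep_set <- strsplit(cfg$clause_separators, "")[[1]]
  is_sep <- chars %in% sep_set
  n <- length(chars)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (is_sep[i]) { i <- i + 1L; next }
    j <- i
    while (j <= n && !is_sep[j]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j - 1L)  # 1-based inclusive
    i <- j
  }
  out <- list()
  folded <- fold_chars(text)
  for (r in runs) {
    seg <- substr(text, r[1], r[2])
    if (!nzchar(trimws(seg))) next
    fseg <- substr(folded, r[1], r[2])
    # split before connective tokens inside the run
    cut <- integer(0)
    for (cue in cfg$connectives) {
      m <- gregexpr(paste0("\\b", regex_escape(cue), "\\b"),
                    fseg, perl = TRUE)[[1]]
      if (m[1] != -1L) cut <- c(cut, as.integer(m))
    }
    cut <- sort(unique(cut[cut > 1L]))
    starts <- c(1L, cut)
    ends <- c(cut - 1L, nchr(seg))
    for (k in seq_along(starts)) {
      piece <- substr(seg, starts[k], ends[k])
      if (!nzchar(trimws(piece))) next
      out[[length(out) + 1L]] <- data.frame(
        clause = piece,
        start = r[1] + starts[k] - 2L,        # 0-based
        end = r[1] + ends[k] - 1L,            # half-open
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(clause = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Match lexicon surfaces in a clause
#'
#' Greedy leftmost-longest dictionary matching over the normalized clause
#' (case- and width-folded in place, so offsets are preserved). Matches
#' never overlap, and at every position the longest indexed surface wins —
#' this is what implements the annotation rule that fixed phrases are
#' extracted whole, at the coarsest granularity, rather than split into
#' their parts. Matches whose edges touch adjacent Latin letters/digits are
#' rejected (no matching inside a longer word).
#'
#' @param clause Clause text.
#' @param index An `episemio_surface_index`.
#' @param offset Document offset (0-based) of the clause start; added to the
#'   returned spans so they index into the full document.
#' @return Mention data frame: `surface` (raw text slice), `start`, `end`
#'   (0-based half-open), `term_id`, `category`, `status` (`NA`, assigned
#'   later).
#' @export
match_terms <- function(clause, index, offset = 0L) {
  stopifnot(inherits(index, "episemio_surface_index"))
  norm <- fold_chars(clause)
  n <- nchr(norm)
  if (n == 0L || !nrow(index$entries)) return(empty_mentions())
  lengths <- index$lengths
  res <- list()
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in lengths) {
      if (L > n - i + 1L) next
      cand <- substr(norm, i, i + L - 1L)
      hit <- get0(cand, envir = index$lookup, inherits = FALSE)
      if (is.null(hit)) next
      # word-boundary guard for alphanumeric edges
      first_ch <- substr(cand, 1L, 1L)
      last_ch <- substr(cand, L, L)
      if (grepl("[a-z0-9]", first_ch) && i > 1L &&
          grepl("[a-z0-9]", substr(norm, i - 1L, i - 1L))) next
      if (grepl("[a-z0-9]", last_ch) && i + L <= n &&
          grepl("[a-z0-9]", substr(norm, i + L, i + L))) next
      res[[length(res) + 1L]] <- data.frame(
        surface = substr(clause, i, i + L - 1L),
        start = offset + i - 1L, end = offset + i + L - 1L,
        term_id = hit[1], category = hit[2], status = NA_character_,
        stringsAsFactors = FALSE)
      i <- i + L
      matched <- TRUE
      break
    }
    if (!matched) i <- i + 1L
  }
  if (!length(res)) return(empty_mentions())
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

# Tokenize folded text into alphanumeric tokens with 1-based start offsets.
tokenize_folded <- function(folded) {
  m <- gregexpr("[a-z0-9]+", folded, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(token = character(0), start = integer(0)))
  data.frame(token = regmatches(folded, list(m))[[1]],
             start = as.integer(m), stringsAsFactors = FALSE)
}

#' Assign occurrence status to a mention
#'
#' Decides `"with"`, `"without"` or `"unknown"` for a mention within its
#' clause. A negation cue within the scope window before the mention yields
#' `"without"`; an uncertainty cue yields `"unknown"`; an intervening
#' connective breaks the scope, and the default is `"with"` (a mentioned
#' symptom is affirmed unless a cue says otherwise). Multi-word cues are
#' supported. For text without token boundaries a character window is used
#' instead of a token window.
#'
#' @param mention One mention row as returned by [match_terms()] with spans
#'   relative to `clause` (i.e. matched with `offset = 0`), or a list with a
#'   `start` field (0-based clause-relative).
#' @param clause The clause text containing the mention.
#' @param cfg An `episemio_rule_config`.
#' @return One of `"with"`, `"without"`, `"unknown"`.
#' @export
#' @examples
#' cfg <- default_rule_config()
#' lx <- default_semiology_lexicon()
#' idx <- build_surface_index(lx, "en")
#' m <- match_terms("without loss of consciousness", idx)
#' assign_status(m[1, ], "without loss of consciousness", cfg)
assign_status <- function(mention, clause, cfg = default_rule_config()) {
  start0 <- as.integer(mention$start[[1]])  # 0-based, clause-relative
  folded <- fold_chars(clause)
  if (start0 < 0L || start0 > nchr(clause)) stop("mention not within clause")
  pre <- substr(folded, 1L, start0)
  toks <- tokenize_folded(pre)
  cue_words <- function(cues) lapply(strsplit(cues, "\\s+"), identity)
  negs <- cue_words(cfg$negation_cues)
  uncs <- cue_words(cfg$uncertainty_cues)
  cons <- cue_words(cfg$connectives)
  if (nrow(toks) > 0L) {
    nt <- nrow(toks)
    lo <- max(1L, nt - cfg$scope_window + 1L)
    window <- toks$token[lo:nt]
    starts_at <- function(words, j) {
      k <- length(words)
      j + k - 1L <= length(window) &&
        identical(window[j:(j + k - 1L)], words)
    }
    for (j in rev(seq_along(window))) {
      if (any(vapply(cons, starts_at, logical(1), j = j))) return("with")
      if (any(vapply(uncs, starts_at, logical(1), j = j))) return("unknown")
      if (any(vapply(negs, starts_at, logical(1), j = j))) return("without")
    }
    return("with")
  }
  # no tokens (unsegmented CJK): nearest-cue-wins inside a character window
  win <- substr(pre, max(1L, start0 - cfg$scope_window_chars + 1L), start0)
  last_pos <- function(cues) {
    pos <- -1L
    for (cue in cues) {
      m <- gregexpr(cue, win, fixed = TRUE)[[1]]
      if (m[1] != -1L) pos <- max(pos, max(as.integer(m)))
    }
    pos
  }
  pc <- last_pos(cfg$connectives)
  pu <- last_pos(cfg$uncertainty_cues)
  pn <- last_pos(cfg$negation_cues)
  best <- max(pc, pu, pn)
  if (best < 0L) return("with")
  if (best == pc) return("with")
  if (best == pu) return("unknown")
  "without"
}

#' Normalize an episode duration mentioned in a clause
#'
#' Scans for the first duration expression (`"lasting 2 minutes"`,
#' `"30 seconds"`, `"1-2 minutes"`) and converts it to seconds using the
#' unit table (s = 1, min = 60, h = 3600). Numeric ranges normalize to their
#' arithmetic midpoint. Non-numeric durations ("for a while") do not match.
#'
#' @param clause Clause text.
#' @param cfg An `episemio_rule_config`.
#' @return `NULL`, or a list with `raw` (verbatim matched text) and
#'   `seconds` (positive number).
#' @export
#' @examples
#' parse_duration("lasting 2 minutes")$seconds   # 120
#' parse_duration("1-2 minutes")$seconds         # 90
parse_duration <- function(clause, cfg = default_rule_config()) {
  folded <- fold_chars(clause)
  m <- regexec(cfg$duration_pattern, folded, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  groups <- regmatches(folded, list(m))[[1]]
  n1 <- suppressWarnings(as.numeric(groups[2]))
  n2 <- suppressWarnings(as.numeric(groups[3]))
  unit <- sub("s$", "", groups[4])
  unit <- sub("^(sec|min|h(ou)?r).*", "\\1", unit)
  u <- cfg$duration_units[[unit]]
  if (is.na(n1) || is.null(u)) {
    warning("unparseable duration expression skipped: '", groups[1], "'")
    return(NULL)
  }
  value <- if (!is.na(n2) && nzchar(groups[3])) (n1 + n2) / 2 else n1
  raw <- substr(clause, m[1], m[1] + attr(m, "match.length")[1] - 1L)
  list(raw = raw, seconds = value * u)
}

#' Normalize a seizure frequency mentioned in a clause
#'
#' Recognizes `"once a month"`, `"3 times per day"`, `"twice a year"`,
#' `"every 2 weeks"` and converts to events per day using day = 1, week = 7,
#' month = 30, year = 365 days.
#'
#' @inheritParams parse_duration
#' @return `NULL`, or a list with `raw` and `per_day` (positive number).
#' @export
#' @examples
#' parse_frequency("once a month")$per_day   # 1/30
#' parse_frequency("3 times per day")$per_day
parse_frequency <- function(clause, cfg = default_rule_config()) {
  folded <- fold_chars(clause)
  m <- regexec(cfg$frequency_pattern, folded, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    groups <- regmatches(folded, list(m))[[1]]
    count <- switch(groups[2], once = 1, twice = 2, thrice = 3,
                    suppressWarnings(as.numeric(sub("\\s*times?$", "", groups[2]))))
    unit_days <- cfg$frequency_unit_days[[groups[3]]]
    if (is.na(count) || is.null(unit_days)) {
      warning("unparseable frequency expression skipped: '", groups[1], "'")
      return(NULL)
    }
    raw <- substr(clause, m[1], m[1] + attr(m, "match.length")[1] - 1L)
    return(list(raw = raw, per_day = count / unit_days))
  }
  m <- regexec(cfg$frequency_every_pattern, folded, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  groups <- regmatches(folded, list(m))[[1]]
  n <- suppressWarnings(as.numeric(groups[2]))
  unit_days <- cfg$frequency_unit_days[[sub("s$", "", groups[3])]]
  if (is.na(n) || n <= 0 || is.null(unit_days)) {
    warning("unparseable frequency expression skipped: '", groups[1], "'")
    return(NULL)
  }
  raw <- substr(clause, m[1], m[1] + attr(m, "match.length")[1] - 1L)
  list(raw = raw, per_day = 1 / (n * unit_days))
}

#' Detect temporal anchors in a narrative
#'
#' Finds the time stamps that structure a history ("3 years ago",
#' "2 months before admission", "at onset", temporal adverbs), in document
#' order with strictly increasing offsets; overlapping candidates keep the
#' earliest (longest on ties). A narrative with no explicit cue gets the
#' implicit anchor `"onset"` at offset 0, and an implicit onset anchor is
#' also prepended when no explicit anchor starts the text, so that every
#' character of the narrative falls under some anchor.
#'
#' @inheritParams parse_duration
#' @param text Full narrative text.
#' @return Data frame with columns `anchor` (raw matched string, or
#'   `"onset"`) and `offset` (0-based character offset).
#' @export
detect_timestamps <- function(text, cfg = default_rule_config()) {
  folded <- fold_chars(text)
  pats <- c(cfg$timestamp_patterns,
            if (length(cfg$temporal_adverbs))
              paste0("\\b(?:",
                     paste(cfg$temporal_adverbs, collapse = "|"), ")\\b"))
  hits <- list()
  for (p in pats) {
    m <- gregexpr(p, folded, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      hits[[length(hits) + 1L]] <- c(as.integer(m[k]),
                                     attr(m, "match.length")[k])
    }
  }
  if (length(hits)) {
    h <- do.call(rbind, hits)
    h <- h[order(h[, 1], -h[, 2]), , drop = FALSE]
    keep <- logical(nrow(h))
    last_end <- 0L
    for (k in seq_len(nrow(h))) {
      if (h[k, 1] > last_end) {
        keep[k] <- TRUE
        last_end <- h[k, 1] + h[k, 2] - 1L
      }
    }
    h <- h[keep, , drop = FALSE]
    anchors <- data.frame(
      anchor = vapply(seq_len(nrow(h)), function(k)
        substr(text, h[k, 1], h[k, 1] + h[k, 2] - 1L), character(1)),
      offset = h[, 1] - 1L, stringsAsFactors = FALSE)
  } else {
    anchors <- data.frame(anchor = character(0), offset = integer(0),
                          stringsAsFactors = FALSE)
  }
  if (!nrow(anchors) || anchors$offset[1] > 0L) {
    anchors <- rbind(data.frame(anchor = "onset", offset = 0L,
                                stringsAsFactors = FALSE), anchors)
  }
  anchors
}

new_seizure_record <- function(doc_id, time_stamp, symptoms = empty_mentions(),
                               locations = empty_mentions(),
                               episode_time = NULL, frequency = NULL) {
  structure(list(doc_id = doc_id, time_stamp = time_stamp,
                 symptoms = symptoms, locations = locations,
                 episode_time = episode_time, frequency = frequency),
            class = "episemio_record")
}

#' @export
print.episemio_record <- function(x, ...) {
  cat("<seizure record> doc=", x$doc_id, " @ '", x$time_stamp, "': ",
      nrow(x$symptoms), " symptom(s), ", nrow(x$locations), " location(s)",
      if (!is.null(x$episode_time)) paste0(", ", x$episode_time$seconds, " s"),
      if (!is.null(x$frequency))
        paste0(", ", signif(x$frequency$per_day, 3), "/day"),
      "\n", sep = "")
  invisible(x)
}

#' Extract structured seizure records from one narrative
#'
#' Runs the full rule pipeline on a document: temporal anchors are detected
#' and the text is divided into the segment following each anchor; within a
#' segment, clauses are segmented, lexicon surfaces matched
#' (leftmost-longest), occurrence status assigned to symptom and location
#' mentions, and the first duration and frequency expressions normalized.
#' One record is produced per anchor; every mention, duration and frequency
#' attaches to the nearest preceding anchor. The pipeline is deterministic.
#'
#' @param doc A list or one-row data frame with `doc_id` and `text`.
#' @param lexicon An `episemio_lexicon`.
#' @param cfg An `episemio_rule_config`.
#' @param index Optional prebuilt [build_surface_index()] (saves rebuilding
#'   it per document when looping over a corpus).
#' @return List of `episemio_record` objects, one per temporal anchor;
#'   empty list for empty text.
#' @export
extract_document <- function(doc, lexicon, cfg = default_rule_config(),
                             index = NULL) {
  doc_id <- as.character(doc$doc_id)
  text <- as.character(doc$text)
  if (!nzchar(trimws(text))) return(list())
  if (is.null(index)) index <- build_surface_index(lexicon, cfg$language)
  anchors <- detect_timestamps(text, cfg)
  n_text <- nchr(text)
  seg_start <- anchors$offset
  seg_end <- c(anchors$offset[-1], n_text)
  clauses <- segment_clauses(text, cfg)
  records <- vector("list", nrow(anchors))
  for (a in seq_len(nrow(anchors))) {
    symptoms <- list(); locations <- list()
    episode_time <- NULL; frequency <- NULL
    in_seg <- clauses$start < seg_end[a] & clauses$end > seg_start[a]
    for (ci in which(in_seg)) {
      cl <- clauses$clause[ci]
      mentions <- match_terms(cl, index, offset = clauses$start[ci])
      mentions <- mentions[mentions$start >= seg_start[a] &
                             mentions$start < seg_end[a], , drop = FALSE]
      for (mi in seq_len(nrow(mentions))) {
        mrow <- mentions[mi, , drop = FALSE]
        if (!mrow$category %in% c("symptom", "location")) next
        rel <- mrow
        rel$start <- rel$start - clauses$start[ci]
        mrow$status <- assign_status(rel, cl, cfg)
        if (mrow$category == "symptom") {
          symptoms[[length(symptoms) + 1L]] <- mrow
        } else {
          locations[[length(locations) + 1L]] <- mrow
        }
      }
      # durations/frequencies belong to the segment their clause starts in
      if (clauses$start[ci] >= seg_start[a]) {
        if (is.null(episode_time)) episode_time <- parse_duration(cl, cfg)
        if (is.null(frequency)) frequency <- parse_frequency(cl, cfg)
      }
    }
    bindm <- function(lst) if (length(lst))
      do.call(rbind, c(lst, list(make.row.names = FALSE))) else empty_mentions()
    records[[a]] <- new_seizure_record(
      doc_id, anchors$anchor[a], bindm(symptoms), bindm(locations),
      episode_time, frequency)
  }
  records
}

#' Extract a whole corpus
#'
#' @param docs Data frame of documents (`doc_id`, `text`).
#' @inheritParams extract_document
#' @return Flat list of `episemio_record` across all documents, in document
#'   order.
#' @export
extract_corpus <- function(docs, lexicon, cfg = default_rule_config()) {
  index <- build_surface_index(lexicon, cfg$language)
  out <- list()
  for (i in seq_len(nrow(docs))) {
    out <- c(out, extract_document(docs[i, , drop = FALSE], lexicon, cfg,
                                   index = index))
  }
  out
}

record_to_list <- function(r) {
  mention_list <- function(df) lapply(seq_len(nrow(df)), function(i) list(
    surface = df$surface[i], span = c(df$start[i], df$end[i]),
    term_id = df$term_id[i], category = df$category[i], status = df$status[i]))
  list(doc_id = r$doc_id, time_stamp = r$time_stamp,
       symptoms = mention_list(r$symptoms),
       locations = mention_list(r$locations),
       episode_time = if (is.null(r$episode_time)) NULL else
         list(raw = r$episode_time$raw, seconds = r$episode_time$seconds),
       frequency = if (is.null(r$frequency)) NULL else
         list(raw = r$frequency$raw, per_day = r$frequency$per_day))
}

list_to_record <- function(o) {
  mention_df <- function(lst) {
    if (!length(lst)) return(empty_mentions())
    do.call(rbind, c(lapply(lst, function(m) data.frame(
      surface = m$surface, start = as.integer(m$span[[1]]),
      end = as.integer(m$span[[2]]), term_id = m$term_id,
      category = m$category,
      status = if (is.null(m$status)) NA_character_ else m$status,
      stringsAsFactors = FALSE)), list(make.row.names = FALSE)))
  }
  new_seizure_record(
    as.character(o$doc_id), as.character(o$time_stamp),
    mention_df(o$symptoms), mention_df(o$locations),
    if (is.null(o$episode_time)) NULL else
      list(raw = o$episode_time$raw,
           seconds = as.numeric(o$episode_time$seconds)),
    if (is.null(o$frequency)) NULL else
      list(raw = o$frequency$raw, per_day = as.numeric(o$frequency$per_day)))
}

#' Read and write seizure records as JSON-Lines
#'
#' One JSON object per record with fields `doc_id`, `time_stamp`,
#' `symptoms`, `locations` (mention arrays with `span = [start, end]`),
#' `episode_time` and `frequency`. The same schema is used for gold
#' annotations.
#'
#' @param records List of `episemio_record`.
#' @param path File path.
#' @return `read_records()` returns a list of `episemio_record`.
#' @export
write_records <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (r in records) {
    writeLines(jsonlite::toJSON(record_to_list(r), auto_unbox = TRUE,
                                null = "null", digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l)
    list_to_record(jsonlite::fromJSON(l, simplifyVector = FALSE)))
}
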
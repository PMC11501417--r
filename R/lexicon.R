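# Lexicon data model: terms with bilingual labels and synonyms, arranged in
# a shallow hierarchy, indexed for exact surface-form matching.

#' Term categories recognized by the lexicon
#'
#' Every lexicon term belongs to exactly one category. `symptom` and
#' `location` terms become record content when matched in text; the cue
#' categories (`negation_cue`, `connective`, `temporal_adverb`,
#' `frequency_cue`, `duration_cue`) feed the rule configuration of the
#' extraction engine.
#'
#' @export
LEXICON_CATEGORIES <- c(
  "symptom", "location", "frequency_cue", "duration_cue",
  "negation_cue", "connective", "temporal_adverb"
)

#' Construct a lexicon term
#'
#' A term is an ontology node: an opaque identifier, one canonical label per
#' language, optional synonym lists per language, a category and an optional
#' parent term. The canonical label always counts as a synonym of itself
#' when the surface index is built.
#'
#' @param id Unique term identifier (string).
#' @param labels Named list or character vector, language code to canonical
#'   label.
#' @param synonyms Named list, language code to character vector of synonym
#'   surfaces. May be empty.
#' @param category One of [LEXICON_CATEGORIES].
#' @param parent Parent term id, or `NULL` for a root term.
#' @param attributes Optional named list of free-form attributes (e.g. a
#'   `nature` qualifier on symptom terms).
#' @return An object of class `episemio_term`.
#' @export
#' @examples
#' term("ESO:0001", c(en = "clonic jerking"),
#'      list(en = c("clonic movements", "jerking")), "symptom")
term <- function(id, labels, synonyms = list(), category, parent = NULL,
                 attributes = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  labels <- as.list(labels)
  if (length(labels) == 0L || is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("term '", id, "': labels must be a named (language -> string) list")
  category <- match.arg(category, LEXICON_CATEGORIES)
  synonyms <- lapply(as.list(synonyms), as.character)
  # normalized synonym lists carry no duplicates and never repeat the label
  for (lang in names(synonyms)) {
    syn <- unique(normalize_surface(synonyms[[lang]]))
    lab <- if (!is.null(labels[[lang]])) normalize_surface(labels[[lang]]) else NULL
    synonyms[[lang]] <- setdiff(syn, lab)
  }
  structure(
    list(id = id, labels = lapply(labels, as.character), synonyms = synonyms,
         category = category, parent = if (is.null(parent)) NULL else as.character(parent),
         attributes = attributes),
    class = "episemio_term"
  )
}

#' Construct and validate a lexicon
#'
#' @param terms List of [term()] objects.
#' @param name,version Metadata strings.
#' @param languages Character vector of language codes covered.
#' @return An object of class `episemio_lexicon`.
#'
#' @details Validation enforces: unique term ids; parent references resolve
#' and the parent graph is acyclic; and, within each language, no surface
#' form (label or synonym, after normalization) is claimed by more than one
#' term — a cross-term collision would make dictionary matching ambiguous
#' and is a load error naming both terms.
#' @export
lexicon <- function(terms, name = "lexicon", version = "0.0",
                    languages = NULL) {
  stopifnot(is.list(terms))
  bad <- !vapply(terms, inherits, logical(1), "episemio_term")
  if (any(bad)) stop("terms[[", which(bad)[1], "]] is not an episemio_term")
  ids <- vapply(terms, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(terms) <- ids
  if (is.null(languages))
    languages <- sort(unique(unlist(lapply(terms, function(t)
      union(names(t$labels), names(t$synonyms))))))
  lx <- structure(
    list(terms = terms,
         metadata = list(name = name, version = version, languages = languages)),
    class = "episemio_lexicon"
  )
  validate_lexicon(lx)
  lx
}

validate_lexicon <- function(lx) {
  terms <- lx$terms
  ids <- names(terms)
  for (t in terms) {
    if (!is.null(t$parent) && !t$parent %in% ids)
      stop("term '", t$id, "' has unknown parent '", t$parent, "'")
  }
  # acyclic parent graph
  for (t in terms) {
    seen <- character(0)
    cur <- t$id
    while (!is.null(terms[[cur]]$parent)) {
      if (cur %in% seen)
        stop("parent cycle involving term '", cur, "'")
      seen <- c(seen, cur)
      cur <- terms[[cur]]$parent
    }
  }
  # surface collisions per language (any two terms claiming one surface)
  for (lang in lx$metadata$languages) {
    surf <- surface_table(lx, lang)
    if (nrow(surf)) {
      dup <- surf$surface[duplicated(surf$surface)]
      if (length(dup)) {
        d1 <- unique(dup)[1]
        owners <- unique(surf$term_id[surf$surface == d1])
        stop("surface collision in language '", lang, "': '", d1,
             "' claimed by terms ", paste(owners, collapse = " and "))
      }
    }
  }
  invisible(lx)
}

# All (normalized surface, term_id, category) rows for one language.
surface_table <- function(lx, language) {
  rows <- lapply(lx$terms, function(t) {
    lab <- t$labels[[language]]
    syn <- t$synonyms[[language]]
    surfaces <- unique(c(
      if (!is.null(lab)) normalize_surface(lab),
      if (!is.null(syn)) normalize_surface(syn)
    ))
    surfaces <- surfaces[nzchar(surfaces)]
    if (!length(surfaces)) return(NULL)
    data.frame(surface = surfaces, term_id = t$id, category = t$category,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(surface = character(0), term_id = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.episemio_lexicon <- function(x, ...) {
  cat("<episemio_lexicon> '", x$metadata$name, "' v", x$metadata$version,
      ": ", length(x$terms), " terms, languages: ",
      paste(x$metadata$languages, collapse = ", "), "\n", sep = "")
  tab <- table(vapply(x$terms, `[[`, character(1), "category"))
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

#' Load a lexicon from its JSON dialect
#'
#' The on-disk dialect is a single JSON object
#' `{"name", "version", "languages", "terms": [...]}` where each term is
#' `{"id", "labels": {lang: str}, "synonyms": {lang: [str]}, "category",
#' "parent": id|null}`. Loading validates all lexicon invariants; a parse
#' failure, duplicate id or cross-term surface collision is fatal.
#'
#' @param path Path to the JSON file.
#' @return An `episemio_lexicon`.
#' @seealso [save_lexicon()], [lexicon_from_tsv()]
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  obj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse lexicon '", path, "': ",
                             conditionMessage(e))
  )
  if (is.null(obj$terms)) stop("lexicon '", path, "' has no 'terms' array")
  terms <- lapply(obj$terms, function(o) {
    tryCatch(
      term(id = o$id, labels = o$labels,
           synonyms = if (is.null(o$synonyms)) list() else o$synonyms,
           category = o$category, parent = o$parent,
           attributes = if (is.null(o$attributes)) list() else o$attributes),
      error = function(e) stop("lexicon '", path, "', term '",
                               if (is.null(o$id)) "?" else o$id, "': ",
                               conditionMessage(e))
    )
  })
  lexicon(terms,
          name = if (is.null(obj$name)) "lexicon" else obj$name,
          version = if (is.null(obj$version)) "0.0" else as.character(obj$version),
          languages = if (is.null(obj$languages)) NULL else unlist(obj$languages))
}

#' @param lx An `episemio_lexicon`.
#' @rdname load_lexicon
#' @export
save_lexicon <- function(lx, path) {
  stopifnot(inherits(lx, "episemio_lexicon"))
  terms <- lapply(unname(lx$terms), function(t) {
    o <- list(id = t$id, labels = t$labels, synonyms = t$synonyms,
              category = t$category,
              parent = if (is.null(t$parent)) NA else t$parent)
    if (length(t$attributes)) o$attributes <- t$attributes
    o
  })
  obj <- list(name = lx$metadata$name, version = lx$metadata$version,
              languages = lx$metadata$languages, terms = terms)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null",
                           pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Import/export the 4-column TSV curation format
#'
#' A flat spreadsheet-friendly view: columns `id`, `lang`, `surface`,
#' `category`. The first surface seen for an (id, lang) pair becomes the
#' canonical label; later rows become synonyms. Hierarchy and attributes are
#' not carried by this format.
#'
#' @param path TSV file path.
#' @param lx Lexicon to export.
#' @param name,version Metadata for the imported lexicon.
#' @return `lexicon_from_tsv()` returns an `episemio_lexicon`.
#' @export
lexicon_from_tsv <- function(path, name = "lexicon", version = "0.0") {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("id", "lang", "surface", "category")
  if (!all(need %in% names(df)))
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  terms <- lapply(split(df, df$id), function(rows) {
    cats <- unique(rows$category)
    if (length(cats) != 1L)
      stop("term '", rows$id[1], "' has conflicting categories in TSV")
    labels <- list(); synonyms <- list()
    for (lang in unique(rows$lang)) {
      ss <- rows$surface[rows$lang == lang]
      labels[[lang]] <- ss[1]
      if (length(ss) > 1L) synonyms[[lang]] <- ss[-1]
    }
    term(rows$id[1], labels, synonyms, cats)
  })
  lexicon(unname(terms), name = name, version = version)
}

#' @rdname lexicon_from_tsv
#' @export
lexicon_to_tsv <- function(lx, path) {
  stopifnot(inherits(lx, "episemio_lexicon"))
  rows <- list()
  for (t in lx$terms) {
    for (lang in names(t$labels))
      rows[[length(rows) + 1L]] <- data.frame(
        id = t$id, lang = lang, surface = t$labels[[lang]],
        category = t$category, stringsAsFactors = FALSE)
    for (lang in names(t$synonyms)) for (s in t$synonyms[[lang]])
      rows[[length(rows) + 1L]] <- data.frame(
        id = t$id, lang = lang, surface = s,
        category = t$category, stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Deduplicate raw annotated surfaces into synonym sets
#'
#' Collapses the raw surface forms collected during annotation into synonym
#' sets keyed by canonical term, the consolidation step that turns thousands
#' of annotated spans into a compact lexicon. Surfaces are normalized
#' ([normalize_surface()]) and then resolved through a seed mapping of
#' normalized surface to term id; surfaces the mapping does not cover are
#' returned in a residual list for manual review rather than dropped.
#'
#' @param raw Character vector of raw annotated surfaces (one language at a
#'   time).
#' @param seed_map Named character vector: normalized surface -> term id.
#' @return List with `sets` (named list, term id -> character vector of
#'   distinct normalized surfaces) and `residual` (character vector of
#'   distinct unmapped normalized surfaces). The sets plus the residual
#'   partition the distinct normalized input surfaces.
#' @export
#' @examples
#' deduplicate_synonyms(c("Clonic", "clonic ", "CLONIC"), c(clonic = "T1"))
deduplicate_synonyms <- function(raw, seed_map) {
  stopifnot(is.character(raw), length(raw) > 0L)
  if (is.null(names(seed_map)) || any(!nzchar(names(seed_map))))
    stop("seed_map must be a named (surface -> term id) character vector")
  names(seed_map) <- normalize_surface(names(seed_map))
  norm <- unique(normalize_surface(raw))
  norm <- norm[nzchar(norm)]
  hit <- norm %in% names(seed_map)
  assigned <- norm[hit]
  sets <- split(assigned, unname(seed_map[assigned]))
  list(sets = lapply(sets, unname), residual = norm[!hit])
}

#' Build an exact-match surface index for one language
#'
#' Flattens a lexicon into the lookup structure the matcher consumes: every
#' canonical label and synonym of every term appears exactly once, keyed by
#' its normalized surface, together with the owning term id and category.
#' Surfaces are retrievable longest-first, which is what guarantees
#' leftmost-longest (coarsest-granularity) matching downstream.
#'
#' @param lx An `episemio_lexicon`.
#' @param language Language code; must be listed in the lexicon metadata.
#' @return An object of class `episemio_surface_index` with fields
#'   `language`, `entries` (data frame `surface`, `term_id`, `category`,
#'   sorted by decreasing surface length), `max_surface_length`, and a
#'   hashed environment for O(1) lookup.
#' @export
build_surface_index <- function(lx, language) {
  stopifnot(inherits(lx, "episemio_lexicon"))
  if (!language %in% lx$metadata$languages)
    stop("language '", language, "' not present in lexicon (has: ",
         paste(lx$metadata$languages, collapse = ", "), ")")
  entries <- surface_table(lx, language)
  entries <- entries[order(-nchr(entries$surface), entries$surface), , drop = FALSE]
  rownames(entries) <- NULL
  lookup <- new.env(parent = emptyenv(), size = max(29L, nrow(entries)))
  for (i in seq_len(nrow(entries)))
    assign(entries$surface[i],
           c(entries$term_id[i], entries$category[i]), envir = lookup)
  structure(
    list(language = language, entries = entries,
         max_surface_length = if (nrow(entries)) max(nchr(entries$surface)) else 0L,
         lengths = sort(unique(nchr(entries$surface)), decreasing = TRUE),
         lookup = lookup),
    class = "episemio_surface_index"
  )
}

#' @export
print.episemio_surface_index <- function(x, ...) {
  cat("<episemio_surface_index> lang=", x$language, ", ",
      nrow(x$entries), " surfaces, max length ", x$max_surface_length,
      "\n", sep = "")
  invisible(x)
}
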
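# Synthetic narratives with exact gold annotations and labeled cohorts with
# known class-conditional structure, so extraction and classification can be
# validated end-to-end without any clinical data.

#' Built-in bilingual seizure-semiology lexicon
#'
#' A compact lexicon of common seizure signs (with synonyms), seizure
#' sites, and cue terms, in English with Chinese labels on the core
#' symptom terms. It is the default vocabulary of the synthetic-narrative
#' generator and a realistic stand-in for a curated semiology ontology:
#' two parent terms carry a shallow hierarchy, and every canonical label
#' is indexable alongside its synonyms.
#'
#' @return An `episemio_lexicon`.
#' @export
default_semiology_lexicon <- function() {
  S <- function(id, en, syn = character(0), zh = NULL, parent = NULL)
    term(id, c(en = en, if (!is.null(zh)) c(zh = zh)),
         if (length(syn)) list(en = syn) else list(),
         "symptom", parent = parent)
  L <- function(id, en) term(id, c(en = en), list(), "location")
  terms <- list(
    # signs typical of generalized onset
    S("ESO:S001", "clonic jerking", c("clonic movements", "rhythmic jerking"),
      zh = "阵挛", parent = "ESO:S101"),
    S("ESO:S002", "tonic stiffening", c("tonic contraction"),
      zh = "强直", parent = "ESO:S101"),
    S("ESO:S003", "loss of consciousness", c("unconsciousness"),
      zh = "意识丧失"),
    S("ESO:S004", "eyes rolled up", c("upward eye deviation"),
      zh = "双眼上翻"),
    S("ESO:S005", "foaming at mouth", c("frothing at the mouth"),
      zh = "口吐白沫"),
    S("ESO:S006", "fall", c("fell to the ground", "sudden fall"),
      zh = "跌倒"),
    S("ESO:S007", "unresponsive to call", c("unresponsiveness"),
      zh = "呼之不应"),
    S("ESO:S008", "urinary incontinence", c("loss of bladder control")),
    S("ESO:S009", "tongue biting", c("bit the tongue")),
    # signs typical of focal onset
    S("ESO:S010", "lip smacking", c("oropharyngeal automatisms"),
      zh = "咀嚼动作", parent = "ESO:S100"),
    S("ESO:S011", "hand rubbing", c("manual automatisms"),
      parent = "ESO:S100"),
    S("ESO:S012", "staring", c("blank stare", "staring spells")),
    S("ESO:S013", "deja vu", c("sense of familiarity")),
    S("ESO:S014", "epigastric rising sensation",
      c("rising abdominal sensation")),
    S("ESO:S015", "unilateral twitching", c("one-sided twitching")),
    S("ESO:S016", "speech arrest", c("unable to speak")),
    S("ESO:S017", "head turning", c("head version")),
    S("ESO:S018", "fear", c("sudden fear")),
    S("ESO:S019", "numbness", c("tingling")),
    # unspecific accompaniments
    S("ESO:S020", "headache"),
    S("ESO:S021", "vomiting"),
    S("ESO:S022", "drowsiness", c("sleepiness")),
    S("ESO:S023", "fatigue"),
    S("ESO:S024", "cyanosis", c("turned blue")),
    # parents carrying the hierarchy
    S("ESO:S100", "automatism", c("automatisms")),
    S("ESO:S101", "convulsion", c("convulsions")),
    # seizure sites
    L("ESO:L001", "left arm"), L("ESO:L002", "right arm"),
    L("ESO:L003", "left leg"), L("ESO:L004", "right leg"),
    L("ESO:L005", "face"), L("ESO:L006", "head"),
    L("ESO:L007", "left hand"), L("ESO:L008", "right hand"),
    # cue terms (the engine also has built-in cue lists)
    term("ESO:N001", c(en = "without"), list(), "negation_cue"),
    term("ESO:N002", c(en = "no"), list(), "negation_cue"),
    term("ESO:N003", c(en = "denied"), list(), "negation_cue"),
    term("ESO:C001", c(en = "but"), list(), "connective"),
    term("ESO:C002", c(en = "however"), list(), "connective"),
    term("ESO:T001", c(en = "initially"), list(), "temporal_adverb"),
    term("ESO:T002", c(en = "subsequently"), list(), "temporal_adverb"),
    term("ESO:D001", c(en = "lasting"), list(), "duration_cue"),
    term("ESO:F001", c(en = "seizure frequency"), list(), "frequency_cue")
  )
  lexicon(terms, name = "synthetic seizure semiology lexicon",
          version = "1.0", languages = c("en", "zh"))
}

#' Default class-conditional symptom probabilities
#'
#' Bernoulli presence probabilities per symptom term for generalized vs
#' focal documents, aligned with [default_semiology_lexicon()]. The strong
#' markers on either side (clonic jerking, tonic stiffening, loss of
#' consciousness, eyes rolled up, foaming at mouth vs automatisms, deja
#' vu, unilateral twitching, ...) make the two classes well separated,
#' while unspecific accompaniments carry no signal.
#'
#' @return Data frame with columns `term_id`, `p_generalized`, `p_focal`.
#' @export
default_symptom_probs <- function() {
  tab <- rbind(
    c("ESO:S001", .80, .10), c("ESO:S002", .75, .10), c("ESO:S003", .85, .25),
    c("ESO:S004", .60, .08), c("ESO:S005", .55, .05), c("ESO:S006", .50, .10),
    c("ESO:S007", .65, .15), c("ESO:S008", .35, .05), c("ESO:S009", .40, .05),
    c("ESO:S010", .05, .45), c("ESO:S011", .05, .35), c("ESO:S012", .15, .55),
    c("ESO:S013", .02, .30), c("ESO:S014", .02, .35), c("ESO:S015", .05, .50),
    c("ESO:S016", .05, .30), c("ESO:S017", .05, .40), c("ESO:S018", .05, .25),
    c("ESO:S019", .05, .35), c("ESO:S020", .25, .25), c("ESO:S021", .10, .10),
    c("ESO:S022", .30, .30), c("ESO:S023", .20, .20), c("ESO:S024", .30, .15),
    c("ESO:S100", .05, .20), c("ESO:S101", .30, .05)
  )
  data.frame(term_id = tab[, 1],
             p_generalized = as.numeric(tab[, 2]),
             p_focal = as.numeric(tab[, 3]),
             stringsAsFactors = FALSE)
}

#' Specify a synthetic cohort
#'
#' Collects every knob of the generator: cohort size, class prior,
#' class-conditional symptom probabilities, how often narratives carry
#' pertinent negatives and uncertainty hedges, how many temporal anchors a
#' history has, and how often durations and frequencies are stated. All
#' randomness flows from the single mandatory seed.
#'
#' @param n_docs Number of documents (>= 2).
#' @param seed Mandatory integer seed.
#' @param class_prior Probability of the `generalized` class; the default
#'   is the 2632/6489 mix of a classified inpatient cohort.
#' @param p_symptom_given_class Data frame (`term_id`, `p_generalized`,
#'   `p_focal`); defaults to [default_symptom_probs()].
#' @param negation_rate Probability per anchor of a pertinent-negative
#'   sentence about an absent symptom.
#' @param uncertainty_rate Probability per anchor of a hedged mention of an
#'   absent symptom.
#' @param p_location Probability a planted symptom carries a seizure site.
#' @param anchors_per_doc Integer range `c(min, max)` of temporal anchors.
#' @param p_duration,p_frequency Probability per anchor of an episode
#'   duration / seizure frequency phrase.
#' @param p_unclassified Probability the diagnosis string is too vague to
#'   classify.
#' @param language Narrative language (templates ship in English).
#' @return An `episemio_cohort_spec` list.
#' @export
cohort_spec <- function(n_docs, seed,
                        class_prior = 2632 / 6489,
                        p_symptom_given_class = default_symptom_probs(),
                        negation_rate = 0.3,
                        uncertainty_rate = 0.05,
                        p_location = 0.4,
                        anchors_per_doc = c(1L, 3L),
                        p_duration = 0.7,
                        p_frequency = 0.6,
                        p_unclassified = 0,
                        language = "en") {
  stopifnot(n_docs >= 2, length(seed) == 1L, is.finite(seed))
  probs <- c(class_prior, negation_rate, uncertainty_rate, p_location,
             p_duration, p_frequency, p_unclassified,
             p_symptom_given_class$p_generalized,
             p_symptom_given_class$p_focal)
  stopifnot(all(probs >= 0 & probs <= 1))
  stopifnot(length(anchors_per_doc) == 2L,
            anchors_per_doc[1] >= 1L,
            anchors_per_doc[2] >= anchors_per_doc[1])
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 class_prior = class_prior,
                 p_symptom_given_class = p_symptom_given_class,
                 negation_rate = negation_rate,
                 uncertainty_rate = uncertainty_rate,
                 p_location = p_location,
                 anchors_per_doc = as.integer(anchors_per_doc),
                 p_duration = p_duration, p_frequency = p_frequency,
                 p_unclassified = p_unclassified, language = language),
            class = "episemio_cohort_spec")
}

anchor_phrases <- function() {
  c("10 years ago", "7 years ago", "5 years ago", "3 years ago",
    "2 years ago", "1 year ago", "8 months ago", "6 months ago",
    "3 months ago", "2 months ago", "1 month ago", "2 weeks ago",
    "3 days ago")
}

duration_phrases <- function() {
  list(list(raw = "10 seconds", seconds = 10),
       list(raw = "30 seconds", seconds = 30),
       list(raw = "90 seconds", seconds = 90),
       list(raw = "2 minutes", seconds = 120),
       list(raw = "1-2 minutes", seconds = 90),
       list(raw = "3 minutes", seconds = 180),
       list(raw = "5 to 10 minutes", seconds = 450),
       list(raw = "1 hour", seconds = 3600))
}

frequency_phrases <- function() {
  list(list(raw = "once a month", per_day = 1 / 30),
       list(raw = "3 times per day", per_day = 3),
       list(raw = "twice a year", per_day = 2 / 365),
       list(raw = "once a week", per_day = 1 / 7),
       list(raw = "2 times per month", per_day = 2 / 30),
       list(raw = "once every 2 weeks", per_day = 1 / 14))
}

diagnosis_strings <- function(class, unclassified = FALSE) {
  if (unclassified)
    return(sample(c("epilepsy, unspecified", "seizure disorder nos"), 1))
  if (class == "generalized")
    sample(c("generalized epilepsy", "generalized tonic-clonic epilepsy",
             "idiopathic generalized epilepsy", "absence epilepsy"), 1)
  else
    sample(c("focal epilepsy", "focal epilepsy with impaired awareness",
             "temporal lobe epilepsy", "frontal lobe epilepsy"), 1)
}

# pick the planted surface for a term: canonical label or a synonym
pick_surface <- function(lx, term_id, language) {
  t <- lx$terms[[term_id]]
  surfaces <- c(normalize_surface(t$labels[[language]]),
                t$synonyms[[language]])
  surfaces[sample.int(length(surfaces), 1)]
}

#' Render a narrative plan into text with exact gold annotations
#'
#' Turns a structured plan (anchors, affirmed/negated/uncertain symptom
#' mentions with optional sites, duration and frequency phrases) into
#' running text using fixed templates that only ever use lexicon surfaces
#' for clinical content and configured cues for negation/uncertainty. The
#' character span of every planted surface is tracked during assembly, so
#' the returned gold records are exact by construction: running
#' [extract_document()] with the default rules on the rendered text
#' recovers them verbatim.
#'
#' @param plan A plan list (`doc_id`, `anchors`); see [generate_cohort()],
#'   which builds plans internally.
#' @return List with `text` and `gold` (list of `episemio_record`).
#' @export
render_narrative <- function(plan) {
  txt <- character(1)
  nc <- 0L
  append <- function(s) {
    start <- nc
    txt <<- paste0(txt, s)
    nc <<- nc + nchr(s)
    start
  }
  gold <- list()
  for (ai in seq_along(plan$anchors)) {
    a <- plan$anchors[[ai]]
    if (ai > 1L) append(" ")
    append(a$anchor)
    symptoms <- list(); locations <- list()
    mention <- function(surface, term_id, category, status) {
      st <- append(surface)
      data.frame(surface = surface, start = st, end = st + nchr(surface),
                 term_id = term_id, category = category, status = status,
                 stringsAsFactors = FALSE)
    }
    first_affirmed <- TRUE
    closed <- FALSE  # whether the current sentence is closed by "."
    for (item in a$items) {
      if (item$type == "affirmed") {
        if (first_affirmed) {
          append(", the patient developed ")
          first_affirmed <- FALSE
        } else {
          if (!closed) append(".")
          append(" He also had ")
        }
        symptoms[[length(symptoms) + 1L]] <-
          mention(item$surface, item$term_id, "symptom", "with")
        if (!is.null(item$location)) {
          append(" involving the ")
          locations[[length(locations) + 1L]] <-
            mention(item$location$surface, item$location$term_id,
                    "location", "with")
        }
        closed <- FALSE
      }
    }
    if (first_affirmed) append(", he remained largely stable")
    if (!is.null(a$duration)) {
      append(", lasting ")
      dstart <- append(a$duration$raw)
      a$duration$span <- c(dstart, dstart + nchr(a$duration$raw))
    }
    if (!is.null(a$frequency)) {
      append(", about ")
      fstart <- append(a$frequency$raw)
      a$frequency$span <- c(fstart, fstart + nchr(a$frequency$raw))
    }
    append(".")
    for (item in a$items) {
      if (item$type == "negated") {
        lead <- if (isTRUE(item$variant)) " He denied " else " There was no "
        append(lead)
        symptoms[[length(symptoms) + 1L]] <-
          mention(item$surface, item$term_id, "symptom", "without")
        append(".")
      } else if (item$type == "uncertain") {
        append(" Possibly accompanied by ")
        symptoms[[length(symptoms) + 1L]] <-
          mention(item$surface, item$term_id, "symptom", "unknown")
        append(".")
      }
    }
    bindm <- function(lst) if (length(lst))
      do.call(rbind, c(lst, list(make.row.names = FALSE))) else empty_mentions()
    # order mentions by document offset, as the extractor reports them
    sy <- bindm(symptoms); sy <- sy[order(sy$start), , drop = FALSE]
    rownames(sy) <- NULL
    gold[[ai]] <- new_seizure_record(
      plan$doc_id, a$anchor, sy, bindm(locations),
      if (is.null(a$duration)) NULL else
        list(raw = a$duration$raw, seconds = a$duration$seconds),
      if (is.null(a$frequency)) NULL else
        list(raw = a$frequency$raw, per_day = a$frequency$per_day))
  }
  list(text = txt, gold = gold)
}

#' Generate a synthetic cohort with gold annotations
#'
#' Samples, for each document, an epilepsy class, symptom presences from
#' the class-conditional probabilities, temporal anchors, seizure sites,
#' episode durations, frequencies, pertinent negatives and uncertainty
#' hedges, then renders each plan into text ([render_narrative()]). The
#' result bundles the documents (with diagnosis strings), the exact gold
#' records, the labels, and the planted binary feature matrix, which by
#' construction equals what [build_feature_matrix()] produces from the
#' gold records.
#'
#' @param spec An [cohort_spec()].
#' @param lexicon Lexicon the templates draw surfaces from; defaults to
#'   [default_semiology_lexicon()].
#' @return An `episemio_gold_bundle`: `documents` (data frame `doc_id`,
#'   `text`, `diagnosis`), `gold` (list of records), `labels` (data frame
#'   `doc_id`, `class`), `planted` (`episemio_feature_matrix`), `spec`.
#' @export
generate_cohort <- function(spec, lexicon = default_semiology_lexicon()) {
  stopifnot(inherits(spec, "episemio_cohort_spec"))
  vocab <- symptom_vocabulary(lexicon, spec$language)
  probs <- spec$p_symptom_given_class
  if (!all(probs$term_id %in% vocab$term_id))
    stop("p_symptom_given_class refers to term(s) absent from the lexicon: ",
         paste(setdiff(probs$term_id, vocab$term_id), collapse = ", "))
  with_seed(spec$seed, {
    docs <- vector("list", spec$n_docs)
    gold <- list()
    classes <- character(spec$n_docs)
    planted <- matrix(0L, spec$n_docs, nrow(vocab),
                      dimnames = list(NULL, vocab$term_id))
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%05d", d)
      cls <- if (stats::runif(1) < spec$class_prior) "generalized" else "focal"
      classes[d] <- cls
      p <- if (cls == "generalized") probs$p_generalized else probs$p_focal
      present <- probs$term_id[stats::runif(nrow(probs)) < p]
      planted[d, present] <- 1L
      n_pool <- spec$anchors_per_doc[1]:spec$anchors_per_doc[2]
      n_anchor <- n_pool[sample.int(length(n_pool), 1)]
      pool <- anchor_phrases()
      anchors_sel <- sort(sample.int(length(pool), n_anchor))
      assign_to <- if (length(present))
        sample.int(n_anchor, length(present), replace = TRUE) else integer(0)
      absent <- setdiff(probs$term_id, present)
      anchors <- vector("list", n_anchor)
      for (ai in seq_len(n_anchor)) {
        items <- list()
        for (tid in present[assign_to == ai]) {
          loc <- NULL
          if (stats::runif(1) < spec$p_location) {
            loc_ids <- names(lexicon$terms)[vapply(lexicon$terms, function(t)
              t$category == "location", logical(1))]
            lid <- loc_ids[sample.int(length(loc_ids), 1)]
            loc <- list(term_id = lid,
                        surface = pick_surface(lexicon, lid, spec$language))
          }
          items[[length(items) + 1L]] <- list(
            type = "affirmed", term_id = tid,
            surface = pick_surface(lexicon, tid, spec$language),
            location = loc)
        }
        if (length(absent) && stats::runif(1) < spec$negation_rate) {
          tid <- absent[sample.int(length(absent), 1)]
          items[[length(items) + 1L]] <- list(
            type = "negated", term_id = tid,
            surface = pick_surface(lexicon, tid, spec$language),
            variant = stats::runif(1) < 0.5)
          absent <- setdiff(absent, tid)
        }
        if (length(absent) && stats::runif(1) < spec$uncertainty_rate) {
          tid <- absent[sample.int(length(absent), 1)]
          items[[length(items) + 1L]] <- list(
            type = "uncertain", term_id = tid,
            surface = pick_surface(lexicon, tid, spec$language))
          absent <- setdiff(absent, tid)
        }
        dur <- NULL; freq <- NULL
        if (stats::runif(1) < spec$p_duration) {
          dp <- duration_phrases()
          dur <- dp[[sample.int(length(dp), 1)]]
        }
        if (stats::runif(1) < spec$p_frequency) {
          fp <- frequency_phrases()
          freq <- fp[[sample.int(length(fp), 1)]]
        }
        anchors[[ai]] <- list(anchor = pool[anchors_sel[ai]], items = items,
                              duration = dur, frequency = freq)
      }
      rendered <- render_narrative(list(doc_id = doc_id, anchors = anchors))
      unclassified <- stats::runif(1) < spec$p_unclassified
      docs[[d]] <- data.frame(
        doc_id = doc_id, text = rendered$text,
        diagnosis = diagnosis_strings(cls, unclassified),
        stringsAsFactors = FALSE)
      gold <- c(gold, rendered$gold)
    }
    documents <- do.call(rbind, c(docs, list(make.row.names = FALSE)))
    rownames(planted) <- documents$doc_id
    labels <- data.frame(doc_id = documents$doc_id, class = classes,
                         stringsAsFactors = FALSE)
    fm <- structure(list(doc_ids = documents$doc_id, X = planted,
                         y = factor(classes,
                                    levels = c("generalized", "focal"))),
                    class = "episemio_feature_matrix")
    structure(list(documents = documents, gold = gold, labels = labels,
                   planted = fm, spec = spec),
              class = "episemio_gold_bundle")
  })
}

#' @export
print.episemio_gold_bundle <- function(x, ...) {
  cat("<episemio_gold_bundle> ", nrow(x$documents), " documents, ",
      length(x$gold), " gold records; classes: ",
      paste(sprintf("%s=%d", names(table(x$labels$class)),
                    table(x$labels$class)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Write a gold bundle to a directory
#'
#' Writes `docs.jsonl`, `gold.jsonl`, `labels.csv` and
#' `planted_matrix.csv`.
#'
#' @param bundle An `episemio_gold_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_documents(bundle$documents, file.path(dir, "docs.jsonl"))
  write_records(bundle$gold, file.path(dir, "gold.jsonl"))
  utils::write.csv(bundle$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE)
  write_feature_matrix(bundle$planted, file.path(dir, "planted_matrix.csv"))
  invisible(dir)
}

#' Simulate an inter-annotator agreement exercise
#'
#' Emulates slipping identical records to several annotators: a sample of
#' gold records is drawn, each symptom mention's occurrence status becomes
#' one item, and each simulated annotator reports the true status with
#' probability `1 - noise_rate` (otherwise one of the other categories,
#' uniformly). The result feeds [fleiss_kappa()] directly.
#'
#' @param gold List of gold `episemio_record`.
#' @param n Number of records to sample.
#' @param n_annotators Raters per item (>= 2).
#' @param noise_rate Per-rater probability of reporting a wrong status.
#'   Because affirmed mentions dominate the status distribution, chance
#'   agreement is high and kappa is sensitive to small error rates; the
#'   1% default models trained annotators and sits in the near-perfect
#'   band.
#' @param seed Integer seed.
#' @return Integer matrix (items x 3 status categories) of rating counts.
#' @export
inject_agreement_sample <- function(gold, n = 50L, n_annotators = 4L,
                                    noise_rate = 0.01, seed = 1L) {
  stopifnot(n <= length(gold), n_annotators >= 2L,
            noise_rate >= 0, noise_rate <= 1)
  cats <- c("with", "without", "unknown")
  with_seed(seed, {
    recs <- gold[sample.int(length(gold), n)]
    truth <- unlist(lapply(recs, function(r) r$symptoms$status))
    if (!length(truth))
      stop("sampled records contain no symptom mentions to rate")
    ratings <- matrix(0L, length(truth), length(cats),
                      dimnames = list(NULL, cats))
    for (i in seq_along(truth)) {
      for (a in seq_len(n_annotators)) {
        label <- if (stats::runif(1) < noise_rate) {
          sample(setdiff(cats, truth[i]), 1)
        } else {
          truth[i]
        }
        ratings[i, label] <- ratings[i, label] + 1L
      }
    }
    ratings
  })
}

#' Monte-Carlo estimate of the Bayes error of a cohort specification
#'
#' Under the generator's model, symptom presences are independent
#' Bernoulli given the class, so the exact posterior is available in
#' closed form; the irreducible misclassification rate of the Bayes rule
#' is estimated by simulation. Used to verify that a specification is
#' separable before asking a classifier to recover it.
#'
#' @param spec An [cohort_spec()].
#' @param n Simulated documents.
#' @param seed Integer seed.
#' @return Estimated Bayes error rate in `[0, 1]`.
#' @export
estimate_bayes_error <- function(spec, n = 20000L, seed = 1L) {
  probs <- spec$p_symptom_given_class
  pa <- pmin(pmax(probs$p_generalized, 1e-12), 1 - 1e-12)
  pb <- pmin(pmax(probs$p_focal, 1e-12), 1 - 1e-12)
  prior <- spec$class_prior
  with_seed(seed, {
    cls <- stats::runif(n) < prior  # TRUE = generalized
    err <- 0L
    for (i in seq_len(n)) {
      p <- if (cls[i]) pa else pb
      x <- stats::runif(length(p)) < p
      llr <- sum(x * log(pa / pb) + (1 - x) * log((1 - pa) / (1 - pb))) +
        log(prior / (1 - prior))
      if ((llr >= 0) != cls[i]) err <- err + 1L
    }
    err / n
  })
}
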
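---
title: "Methods: lexicon-driven seizure-semiology extraction and stacked classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lexicon-driven seizure-semiology extraction and stacked classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episemio)
```

## The problem

The history of present illness in an epilepsy record narrates, in rough
chronological order, when seizures began, what they looked like, how long
episodes lasted and how often they recurred. Six pieces of information per
seizure episode carry most of the diagnostic signal: the **time stamp**
(where in the illness course the episode sits), the **symptom** (clonic
jerking, staring, automatisms, ...), its anatomical **location**, its
occurrence **status** (affirmed, explicitly denied, or uncertain — the
clinician's pertinent negative must not be read as presence), the
**episode duration**, and the **seizure frequency**. `episemio` extracts
these six slots from free text into one record per temporal anchor, scores
the extraction against gold annotations, and uses the extracted symptom
profile to classify a patient's epilepsy as generalized or focal.

## Extraction model

Extraction is dictionary-driven, not open-vocabulary. A lexicon of
semiology terms — each with canonical labels and synonym lists per
language, a category, and an optional parent — is flattened into a
surface index (`build_surface_index()`). Surfaces are normalized by
trimming, Latin case-folding, and full-width/half-width unification;
case- and width-folding preserve character counts, so the same transform
applies to running text without breaking offsets.

The engine then works clause by clause:

1. **Temporal anchors** (`detect_timestamps()`): regular expressions for
   relative dates ("3 years ago", "2 months before admission") and
   temporal adverbs, in document order. A text with no cue gets the
   implicit anchor `"onset"` at offset 0, as does any text whose first
   anchor is not at the start, so every character falls under some anchor.
2. **Clause segmentation** (`segment_clauses()`): splits at sentence and
   clause punctuation and before logical connectives. This, together with
   cue scoping, replaces dependency parsing; the scope decision is
   confined to `assign_status()` so a parser-backed resolver could be
   swapped in without touching anything else.
3. **Matching** (`match_terms()`): greedy leftmost-longest over the
   surface index. Longest-match implements the annotation principle that
   fixed phrases are extracted whole at the coarsest granularity — "tonic
   clonic" is one mention, never "tonic" plus "clonic". Two terms claiming
   the same surface would make this ambiguous, so that is a lexicon load
   error rather than a runtime tie-break. Matches whose edges touch
   adjacent Latin letters or digits are rejected (no "tonic" inside
   "catatonic").
4. **Status** (`assign_status()`): a negation cue within 6 tokens before a
   mention (10 characters for unsegmented CJK text) marks it `without`; an
   uncertainty cue marks it `unknown`; an intervening connective or clause
   boundary breaks the scope; the default is `with`. The window sizes are
   configurable in `default_rule_config()`.
5. **Normalization**: durations map to seconds (s = 1, min = 60,
   h = 3600), numeric ranges to their arithmetic midpoint ("1–2 minutes"
   → 90 s); frequencies map to events per day with day = 1, week = 7,
   month = 30, year = 365 ("once a month" → 1/30). The midpoint and the
   30/365-day conventions are package conventions; the raw phrase is kept
   verbatim alongside the normalized value so nothing is lost.

Every mention, duration and frequency attaches to the nearest preceding
anchor, giving one `SeizureRecord` per anchor. The pipeline is
deterministic: identical text, lexicon and rules always produce identical
records.

## Evaluation model

`align_elements()` scores one dimension at a time. Records are paired by
document and time stamp; within a paired record the number of correct
elements is the size of a maximum one-to-one matching between gold and
predicted element multisets, which for equality-based matching equals the
multiset intersection (the test suite checks this against brute-force
bipartite matching). The default `term` mode compares concept identity —
term ids, with the status value added for the status dimension — because
span-level agreement is a stricter criterion than concept audits need;
`exact_text` mode is available for such audits.

`prf()` returns unrounded precision, recall and F1. `prf_table()`
additionally reproduces the arithmetic of a typeset performance table:
percentages rounded half-up to integers, and F1 computed from precision
and recall *already rounded to two decimals*. The distinction matters: for
counts like 1126/1325/1219 the unrounded harmonic mean is 0.885 (rounds
to 0.89) while the table convention gives 0.88. Both paths are exposed so
either convention can be audited; the two conventions can also differ by
one final digit when the table value was truncated rather than rounded,
which is why we expose the counts themselves in `evaluate_extraction()`.

Inter-annotator agreement uses Fleiss's κ for a constant number of raters,
with κ = 1 under perfect agreement and an error when only one category is
ever used (chance agreement 1 makes κ undefined).

## Classification model

Documents become a binary matrix over a fixed symptom vocabulary: entry
(i, j) is 1 iff document i contains an affirmed mention of vocabulary term
j. Negated and uncertain mentions encode as 0 — features are presence
indicators, not three-valued. Diagnosis strings map to classes by an
ordered regular-expression table (first match wins; unmatched records are
excluded as unclassified).

The classifier is a two-stage stacked ensemble (`fit_stack()`). Stage 1
runs 5-fold cross-validation inside the training set: each base learner is
fitted on four folds and predicts the held-out fold, so every training row
receives exactly one out-of-fold probability per learner; the same fold
models predict the whole test set, and the test meta-feature is the mean
of the five fold-model predictions (the per-fold test predictions need an
aggregation rule, and the mean is the standard, variance-reducing choice).
Stage 2 fits an L2-regularized logistic regression (ridge, fixed
λ = 0.01, recorded in the model object) on the out-of-fold meta-features.
The default base roster is XGBoost plus a random forest — the pairing that
performs best in practice for this kind of sparse binary profile — with a
single decision tree available as a weaker baseline. Generalized epilepsy
is the positive class throughout, fixing the ROC orientation; AUC is
computed by the rank (Mann–Whitney) formulation with midranks for ties.

Four feature-selection criteria are provided (`select_features()`): ANOVA
F, plug-in mutual information on the 2×2 feature/label table (in nats),
random-forest impurity importance, and recursive feature elimination.
Constant features score zero by convention. With `k` equal to the full
vocabulary, selection is the identity — which is also the best-performing
setting on profiles like these, where individually weak symptoms still
carry complementary signal.

## What the synthetic generator emulates — and what it does not

No clinical corpus ships with the package. `generate_cohort()` emulates
the structure of real histories: per document it samples a class
(prior 2632/6489 ≈ 0.406, the class mix of a classified inpatient
cohort), symptom presences from class-conditional Bernoulli probabilities,
1–3 temporal anchors, seizure sites, duration and frequency phrases,
pertinent negatives about absent symptoms, and occasional uncertainty
hedges; it renders these through fixed English templates that use only
lexicon surfaces and configured cues, tracking the character span of
every planted surface so the gold records are exact by construction.

Default generator parameters are fixed once and documented here: 70% of
anchors carry a duration and 60% a frequency (duration is the more
routinely recorded of the two), 30% of anchors carry a pertinent
negative and 5% an uncertainty hedge, and 40% of planted symptoms carry a
site. The class-conditional probabilities give strong generalized markers
(clonic jerking 0.80 vs 0.10, tonic stiffening 0.75 vs 0.10, ...), strong
focal markers (automatisms, déjà vu, unilateral twitching, ...), and
uninformative accompaniments (headache, vomiting); the resulting Bayes
error, estimated from the closed-form posterior
(`estimate_bayes_error()`), is below 2%, so a correct learner should
recover the classes nearly perfectly.

Because templates are unambiguous and every clinical phrase comes from the
lexicon, extraction on this corpus achieves precision = recall = 1.0 per
dimension, and the planted feature matrix equals
`build_feature_matrix(extract_document(...))` exactly — the full-pipeline
identity. This validates the machinery, not the clinical difficulty: real
narratives contain misspellings, paraphrase outside the lexicon, witness
attribution and parse-dependent scope, so perfect synthetic scores say
nothing about real-world accuracy. They say only that every loss observed
on real text is attributable to language, not to the pipeline.

The agreement simulator treats annotators as noisy channels over the gold
status labels. Affirmed mentions dominate that distribution (roughly 90%
"with"), so chance agreement is high and κ is very sensitive to the error
rate: 3% per-rater noise already drags κ near 0.6, while the 1% default —
a trained-annotator error rate — yields κ ≈ 0.86, in the conventional
near-perfect band. This base-rate sensitivity is a known property of κ
and worth remembering when reading published agreement values.

## Numerical and design choices

- Offsets are 0-based half-open over characters (not bytes), CJK-safe;
  the raw slice at every mention span equals the mention surface.
- Rounding helpers round half away from zero (base R's `round()` is
  banker's rounding, which never produces 0.85 → 85%).
- `split_train_test()` uses per-class `floor(ratio * n)` then tops up by
  largest fractional remainder, so a 7:3 split of 2632 + 3857 gives
  exactly 4542 training and 1947 test rows.
- Stage-1 folds are drawn uniformly; a fold whose training part lacks a
  class triggers a re-draw with a shifted seed, at most five times.
- If every base-model column is constant the meta-learner degenerates to
  an intercept (the training prevalence) rather than failing.
- All stochastic functions take an explicit seed and restore the caller's
  RNG state; `generate_cohort()` is byte-identical for equal seeds.
- Problem sizes used by the validation scripts — 1000 documents for the
  extraction identity, 2000 for classifier recovery across five seeds,
  10000 scores for the null-AUC check — are chosen so that sampling error
  is far from the asserted bounds while a desktop run stays in minutes.

## Known limitations

- English templates only by default; the engine is language-parameterized
  (lexicon plus cue lists, with a character-window scope rule for
  unsegmented text), but no Chinese tokenizer or parser is bundled.
- Negation scope is a token-window heuristic; long-range or syntactically
  embedded negation ("never, in any of these episodes, ...") is out of
  reach without a parser behind the scope interface.
- No coreference, witness attribution, spelling correction or
  abbreviation expansion; unmatched text is silently ignored by design.
- The lexicon hierarchy is metadata only — no reasoning over parents, no
  OWL serialization.
- Continuous features (durations, frequencies) are not used for
  classification; the feature matrix is presence-only.
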
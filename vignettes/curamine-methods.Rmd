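---
title: "Detecting experimental methods and curatable articles: models and design"
author: "curamine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting experimental methods and curatable articles: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curamine)
library(dplyr)
```

## The curation problem

Interaction databases (IntAct, MINT, BioGRID) are filled by curators who
read publications, decide whether an article reports curatable
protein–protein interactions (PPIs), and record which experimental
detection methods — named by PSI-MI `MI:dddd` identifiers — support each
interaction. curamine implements computational support for both decisions:

* **Method detection (IMT)** — a multi-label task: given an article, rank
  the PSI-MI experimental methods it mentions. Training data gives the
  methods of each document but *not* where they are mentioned, which makes
  this as much a document-classification problem as a named-entity one.
* **Article triage (ACT)** — a binary task: does the article contain
  curatable PPIs at all? The positive class is a minority (about 17% in
  the development material this design targets), so balanced measures
  (MCC, AUC iP/R) and threshold handling matter more than raw accuracy.

## Method detection

### Dictionary matching

The PSI-MI ontology supplies, per method, a term name and synonyms, e.g.
`MI:0004` *affinity chromatography technology* with synonyms *affinity
chrom* and *affinity purification*. Full terms are rare in running text,
so `find_matches()` emits three tiers of events:

* **full** — a contiguous occurrence of a complete term or synonym;
* **subset** — more than three distinct words of one term inside a
  sliding ten-token observation window (`subset_min = 4`, `window = 10`);
* **submatch** — any single occurrence of an indexed term word
  (e.g. *purification* alone flags `MI:0004`).

The only stopwords are the prepositions *of* and *in*, which occur inside
many method terms. Tier weights default to full = 1.0, subset = 0.5,
submatch = 0.1; only their ordering is principled (high / mid / low per
occurrence), the values are configuration. Overlapping windows that
capture the same word occurrences are merged into one subset event —
without merging, a single co-occurrence would be counted up to ten times
as the window slides across it, inflating scores quadratically in window
size. Matching runs over the detected methods section by default
(`detect_method_section()`, a small list of case-insensitive heading
regexes with a whole-body fallback), switchable to the whole article.

### Term statistics from the corpus

Submatching has high recall and poor precision: the word *protein* flags
*mammalian protein protein interaction trap* (`MI:0231`) in essentially
every article. Two corpus-estimated statistics repair this:

* `p(method | word)` — document-level: of the training documents
  containing the word, the fraction annotated with the method
  (`estimate_method_given_word()`). Because documents carry several
  methods, these conditionals need not sum to 1 over methods.
* **termness(word)** — token-level: the fraction of the word's
  occurrences that fall in documents annotated with at least one method
  whose term words contain it (`estimate_termness()`); an estimate of the
  probability that an occurrence is actually part of an assigned method
  term.

A document's score for method *m* is the sum over word occurrences of
`p(m | w) × termness(w)`, scaled by a per-method prior weight. The product
of the two statistics is the most direct reading of "summing the values"
of the two named quantities; it is the one genuinely open modelling choice
here, made once and exposed through the fitted tables so alternatives can
be audited.

Three scorers share this summation:

* `score_statistical_dictionary()` — restricted to words of the PSI-MI
  dictionary (matches and submatches);
* `score_corpus_driven()` — no dictionary at all; every word counts
  whenever `p(m|w) > 0.10`, `termness(w) > 0.10` (strict, "above 10%"),
  and the word occurs in at least 5 training documents (inclusive);
* `score_bigram()` — the same construction on adjacent word pairs,
  `p(m | bigram) > 0.10`, each contribution multiplied by
  `1 + log(1 + χ²(bigram))`. The chi-square collocation statistic
  (2×2 contingency of the pair against its parts over all corpus bigrams,
  `chi_square_2x2()`) up-weights genuine multi-word terms; the log damping
  keeps a heavy-tailed statistic from dominating the ranking, and
  `use_colloc = FALSE` recovers the plain bigram model.

`adjust_priors()` maps development-set precision per method to a prior
weight (floored at 0.05), implementing "give low-precision methods lower
weight"; the exact mapping is a design choice, kept monotone and bounded.

### Combination and ranking

`combine_additive()` sums score maps elementwise (the configuration
behind the combined submission run); `combine_average()` min–max
normalizes each map per document before averaging, which is what makes
averaging two systems with incommensurate score scales meaningful.
`rank_predictions()` sorts by score with deterministic tie-breaks (prior
weight, then method id), reports confidence as score over the document
maximum, and optionally cuts at a rank threshold — the trade between the
full-output runs (recall and AUC) and the thresholded runs (F-score).

## Article triage

### Features

* **W** — bag of stems with *cumulative count encoding*: a stem occurring
  three times yields indicator features `protein 1`, `protein 2`,
  `protein 3`, letting a linear model respond to repetition.
* **M** — MeSH expansion. From
  `-Signal Transduction (-drug effects; +physiology)` the extractor emits
  `signal/transduction/drug/effects`, `signal/transduction/physiology`,
  `signal/transduction`, `transduction` (iterative first-word removal),
  `-drug/effects` and `+physiology`.
* **B** — stem bigrams seen at least 3 times in the *training* split
  (`build_bigram_vocab()`); the vocabulary is rebuilt inside every CV
  fold so no test-derived feature can leak.

Word and bigram features are taken from title plus body text. The
PPI-pipeline feature groups of the original system (dependency-parse
scores, protein-pair counts) are outside this package's scope: they
require a full named-entity and parsing pipeline that is a separate
system, not a statistic of the corpus.

### The probabilistic classifier

Binary maximum entropy over indicator features is L2-regularised logistic
regression; `train_maxent()` maximises the penalised likelihood with a
deterministic quasi-Newton optimiser (L-BFGS-B, analytic gradient, bias
unpenalised; defaults `l2 = 1.0`, tolerance `1e-6`, 500 iterations). The
tests verify the optimum against an independent reference optimiser
(ridge-path glmnet at the matched penalty) and recover the weights of a
known generating model (correlation > 0.95 at n = 2000, 20 features). An
optional minimum-feature-count filter exists but defaults to off: global
frequency thresholds were found to hurt the minority class, which is the
class one cares about.

The classifier value in [0, 1] feeds the **discretization threshold
(DTH)** rule: class 1 iff value ≥ DTH, confidence = value for class 1 and
1 − value for class 0. Lowering the DTH below 0.5 boosts the minority
class; `tune_dth()` grid-searches a criterion (MCC by default, ties to
the lowest threshold) and `percentile_dth()` instead fixes the *fraction*
of positive decisions per test subset (ties at the cut value all
classified positive, ceiling rounding), which stabilises comparisons
between feature sets of very different sharpness.

`oversample()` is the competing imbalance treatment: every positive
duplicated ⌊neg/pos⌋ times plus a seeded random remainder taken once
more, so 612 positives against 2979 negatives become 612 × 4 + 531 =
2979. `act_cv()` runs stratified k-fold cross-validation in any of the
three modes, and `paired_feature_test()` compares two systems' per-fold
MCC with a one-sided paired t-test (df = n − 1), reporting the minimally
expected improvement (lower bound of the one-sided 95% CI), per-system
CIs on separately estimated variances, and the Shapiro–Wilk statistic of
the differences.

## Evaluation conventions

* Micro metrics pool all (document, method) pairs; macro averages
  per-document metrics over documents with non-empty gold. The averaging
  unit is the document; per-method breakdowns are a separate report
  (`per_method_report()`), not "macro".
* AUC iP/R: walk the ranked list; interpolated precision at recall r is
  the maximum precision at any recall ≥ r; the AUC is the mean
  interpolated precision over *all* gold positives, so positives never
  retrieved contribute 0. Ties in confidence are broken deterministically
  (method id, then document id), making the AUC invariant to input order.
* MCC with any zero factor in the denominator is defined as 0, so
  degenerate CV folds aggregate without special-casing.
* Metrics with zero denominators are reported `NA` ("undefined"), never
  silently 0.

## What the synthetic generators emulate

`gen_ontology()` / `gen_imt_corpus()` / `gen_act_corpus()` exist so every
pipeline is testable offline, as pure functions of a seeded
`fixture_spec()`:

* method vocabularies with controllable between-method overlap
  (`noise_overlap`), planted into documents at `plant_rate` on top of a
  Zipf-distributed background vocabulary — Zipf so that the frequency
  thresholds (document frequency ≥ 5, bigram count ≥ 3) are exercised by
  construction rather than vacuously;
* a methods-like section with real headings, so zoning runs on every
  generated document;
* an article corpus at a 17% positive rate, the class balance of the
  development material, with interaction-signal stems and MeSH
  descriptors injected at `act_signal_strength`.

Default problem sizes (about 100 documents for the detection experiments,
200 for the classification CV, n = 2000 for parameter recovery) are
chosen so that the statistical claims being tested — top-1 recovery,
MCC near 1 under strong signal, weight correlation — are comfortably
away from their thresholds while the full suite stays quick to run.

What passing these tests shows is that the estimators, scorers and
evaluation measures implement their definitions correctly and that the
pipeline recovers planted structure. What it cannot show is performance
on real biomedical text: generated documents have no syntax, no
polysemy, no genuine MeSH indexing, and a vocabulary many orders of
magnitude smaller than PubMed's. The published benchmark numbers are
therefore not reproduced here beyond the metric identities that follow
deterministically from the printed confusion counts.

## Numerical choices and degenerate inputs

* Thresholds quoted as "above 10%" are strict (`>`); "at least 5
  documents" is inclusive (`≥`).
* Ranking drops zero-score methods; an empty score map yields an empty
  prediction set rather than an error.
* `combine_average()` treats a method absent from a map as score 0 and
  normalizes by the per-document maximum (min–max on non-negative scores).
* The Porter stemmer is implemented in-package (no stemming dependency is
  available); it is deterministic, and idempotence is asserted over the
  generator vocabulary.
* Offsets (token and section spans) are 0-based half-open throughout.
* `oversample()` requires positives to be the strict minority; single-class
  training data, malformed records, out-of-range thresholds and
  zero-length inputs raise immediate, named errors rather than propagating
  NA.

## A worked example

```{r example, eval = FALSE}
spec <- fixture_spec(seed = 1, n_methods = 6, n_docs = 100,
                     plant_rate = 1, methods_per_doc = c(1, 1))
ont  <- gen_ontology(spec)
corp <- gen_imt_corpus(ont, spec)

model <- term_stats_fit(corp$docs, corp$gold, ont)
preds <- imt_predict(corp$docs, model, build_term_index(ont),
                     mode = "combined")
imt_report(preds, corp$gold)

act <- gen_act_corpus(fixture_spec(seed = 2, n_docs = 200,
                                   act_signal_strength = 0.9))
cv <- act_cv(act$docs, act$gold, groups = c("W", "M"), k = 5, seed = 3)
summary(cv$mcc)
```

## Known limitations

* System B of the original submission (an independently developed naive
  Bayes multiclass system) is represented only through the generic
  corpus-driven scorer plus the averaging combiner; its internals were
  never published.
* The extra terminology manually added for specific methods in the
  original system is not shipped; `build_term_index()` accepts a
  user-supplied `extra_synonyms` table instead.
* No smoothing is applied to the probability tables; words unseen in
  training simply contribute nothing.
* The MeSH parser implements the signed textual dialect exactly as far as
  it is documented; qualifiers of any word count are accepted, and
  unparseable lines raise errors rather than being dropped.
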
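# Statistical scoring of experimental methods: corpus-estimated term
# statistics (p(method|word), termness, document frequencies, bigram model
# with chi-square collocation weights, method priors), the three scorers,
# combination, ranking and rank thresholding.

# tokenized zone words per document, as a long tibble (doc_id, word, pos)
corpus_word_table <- function(docs, zone = "methods") {
  texts <- zone_text(docs, zone)
  rows <- purrr::map2(docs$doc_id, texts, function(id, txt) {
    w <- doc_words(txt)
    if (length(w) == 0L) return(NULL)
    tibble::tibble(doc_id = id, word = w, pos = seq_along(w))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(doc_id = character(), word = character(),
                          pos = integer())
  }
  out
}

#' Estimate p(method | word) from a training corpus
#'
#' Document-level counting: `p(m|w)` is the fraction of training documents
#' containing the word `w` that are annotated with method `m`. Entries are
#' stored only when at least one such document exists; absent (method,
#' word) pairs read as probability 0.
#'
#' @param docs training documents tibble.
#' @param gold method gold tibble (`doc_id`, `method_id`).
#' @param zone text zone used for counting (`"methods"` or `"all"`).
#' @return a tibble `method_id`, `word`, `p`, `n_docs_word` (document
#'   frequency of the word).
#' @export
estimate_method_given_word <- function(docs, gold, zone = "methods") {
  if (nrow(docs) == 0L) {
    rlang::abort("estimate_method_given_word(): empty corpus")
  }
  wt <- corpus_word_table(docs, zone)
  doc_word <- dplyr::distinct(wt, .data$doc_id, .data$word)
  df <- dplyr::count(doc_word, .data$word, name = "n_docs_word")
  joint <- doc_word |>
    dplyr::inner_join(gold, by = "doc_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$method_id, .data$word, name = "n_joint")
  joint |>
    dplyr::inner_join(df, by = "word") |>
    dplyr::mutate(p = .data$n_joint / .data$n_docs_word) |>
    dplyr::select("method_id", "word", "p", "n_docs_word")
}

#' Estimate method termness of every corpus word
#'
#' Token-level counting: `termness(w)` is the fraction of the occurrences
#' of `w` in the training corpus that fall in documents annotated with at
#' least one method whose term or synonym words contain `w` (i.e. the
#' probability that an occurrence of the word is actually part of a method
#' term assigned to its document).
#'
#' @param docs,gold,zone as in [estimate_method_given_word()].
#' @param ontology ontology tibble supplying the term/synonym word sets.
#' @return a tibble `word`, `termness`, `n_occ` (total corpus occurrences).
#' @export
estimate_termness <- function(docs, gold, ontology, zone = "methods") {
  wt <- corpus_word_table(docs, zone)
  occ <- dplyr::count(wt, .data$word, name = "n_occ")
  # method -> set of term/synonym words (unfiltered, lowercased)
  mwords <- purrr::pmap(
    list(ontology$method_id, ontology$name, ontology$synonyms),
    function(id, name, syns) {
      w <- unique(unlist(lapply(c(name, syns), function(s) {
        tolower(cm_tokenize(s, stem_tokens = FALSE)$surface)
      })))
      tibble::tibble(method_id = id, word = w)
    }
  ) |> dplyr::bind_rows()
  # doc -> words covered by its gold methods' terms
  doc_term_words <- gold |>
    dplyr::inner_join(mwords, by = "method_id",
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$doc_id, .data$word) |>
    dplyr::mutate(is_term = TRUE)
  term_occ <- wt |>
    dplyr::left_join(doc_term_words, by = c("doc_id", "word")) |>
    dplyr::filter(!is.na(.data$is_term)) |>
    dplyr::count(.data$word, name = "n_term_occ")
  occ |>
    dplyr::left_join(term_occ, by = "word") |>
    dplyr::mutate(
      n_term_occ = dplyr::coalesce(.data$n_term_occ, 0L),
      termness = .data$n_term_occ / .data$n_occ
    ) |>
    dplyr::select("word", "termness", "n_occ")
}

#' Estimate the bigram model and collocation weights
#'
#' `p(method|bigram)` is computed document-level exactly like
#' `p(method|word)`. The collocation weight of a bigram is the chi-square
#' statistic of its 2x2 contingency table over all adjacent bigram tokens
#' of the training zone (occurrences of the pair vs occurrences of each
#' word in other pairs), computed as the direct sum of
#' (observed - expected)^2 / expected.
#'
#' @param docs,gold,zone as in [estimate_method_given_word()].
#' @return a list with `p_bigram` (tibble `method_id`, `w1`, `w2`, `p`)
#'   and `colloc` (tibble `w1`, `w2`, `chi2`).
#' @export
estimate_bigram_stats <- function(docs, gold, zone = "methods") {
  texts <- zone_text(docs, zone)
  bg_rows <- purrr::map2(docs$doc_id, texts, function(id, txt) {
    w <- doc_words(txt)
    bg <- cm_bigrams(w)
    if (nrow(bg) == 0L) return(NULL)
    bg$doc_id <- id
    bg
  })
  bg <- dplyr::bind_rows(bg_rows)
  if (nrow(bg) == 0L) {
    return(list(
      p_bigram = tibble::tibble(method_id = character(), w1 = character(),
                                w2 = character(), p = numeric()),
      colloc = tibble::tibble(w1 = character(), w2 = character(),
                              chi2 = numeric())
    ))
  }
  doc_bg <- dplyr::distinct(bg, .data$doc_id, .data$w1, .data$w2)
  dfb <- dplyr::count(doc_bg, .data$w1, .data$w2, name = "n_docs_bg")
  joint <- doc_bg |>
    dplyr::inner_join(gold, by = "doc_id",
                      relationship = "many-to-many") |>
    dplyr::count(.data$method_id, .data$w1, .data$w2, name = "n_joint")
  p_bigram <- joint |>
    dplyr::inner_join(dfb, by = c("w1", "w2")) |>
    dplyr::mutate(p = .data$n_joint / .data$n_docs_bg) |>
    dplyr::select("method_id", "w1", "w2", "p")

  # chi-square collocation over pooled bigram tokens
  counts <- dplyr::count(bg, .data$w1, .data$w2, name = "o11")
  n_total <- sum(counts$o11)
  c1 <- dplyr::count(bg, .data$w1, name = "n_w1")
  c2 <- dplyr::count(bg, .data$w2, name = "n_w2")
  colloc <- counts |>
    dplyr::inner_join(c1, by = "w1") |>
    dplyr::inner_join(c2, by = "w2") |>
    dplyr::mutate(chi2 = chi_square_2x2(
      .data$o11,
      .data$n_w1 - .data$o11,
      .data$n_w2 - .data$o11,
      n_total - .data$n_w1 - .data$n_w2 + .data$o11
    )) |>
    dplyr::select("w1", "w2", "chi2")
  list(p_bigram = p_bigram, colloc = colloc)
}

#' Chi-square statistic of 2x2 contingency counts
#'
#' Direct evaluation of sum over cells of (O - E)^2 / E, without continuity
#' correction. Vectorised over the four count arguments. Tables with a zero
#' marginal return 0 (observed equals expected degenerately).
#'
#' @param o11,o12,o21,o22 cell counts.
#' @return numeric vector of chi-square statistics.
#' @export
chi_square_2x2 <- function(o11, o12, o21, o22) {
  o11 <- as.numeric(o11); o12 <- as.numeric(o12)
  o21 <- as.numeric(o21); o22 <- as.numeric(o22)
  n <- o11 + o12 + o21 + o22
  r1 <- o11 + o12; r2 <- o21 + o22
  c1 <- o11 + o21; c2 <- o12 + o22
  denom <- r1 * r2 * c1 * c2
  out <- ifelse(denom > 0, n * (o11 * o22 - o12 * o21)^2 / denom, 0)
  as.numeric(out)
}

#' Turn development-set precision into method prior weights
#'
#' Methods that achieved low precision on a development run are
#' down-weighted: the prior weight of a method is its development precision
#' floored at `floor_value`. Methods absent from the table keep weight 1.
#'
#' @param dev_precision tibble `method_id`, `precision` with values in
#'   \[0, 1\].
#' @param floor_value minimum weight (default 0.05).
#' @return tibble `method_id`, `weight`.
#' @export
adjust_priors <- function(dev_precision, floor_value = 0.05) {
  p <- dev_precision$precision
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    rlang::abort("adjust_priors(): precision values must lie in [0, 1]")
  }
  tibble::tibble(method_id = dev_precision$method_id,
                 weight = pmax(floor_value, p))
}

#' Fit the full term-statistics model
#'
#' Bundles [estimate_method_given_word()], [estimate_termness()] and
#' [estimate_bigram_stats()] into one fitted object with (optional) prior
#' weights.
#'
#' @param docs,gold,zone training inputs as in the individual estimators.
#' @param ontology ontology tibble (required for termness and the
#'   dictionary-restricted scorer).
#' @param priors optional prior-weight tibble from [adjust_priors()].
#' @return an object of class `term_stats`.
#' @export
term_stats_fit <- function(docs, gold, ontology, zone = "methods",
                           priors = NULL) {
  pw <- estimate_method_given_word(docs, gold, zone)
  tn <- estimate_termness(docs, gold, ontology, zone)
  bs <- estimate_bigram_stats(docs, gold, zone)
  structure(
    list(p_word = pw, termness = tn, doc_freq = pw |>
           dplyr::distinct(.data$word, .data$n_docs_word),
         p_bigram = bs$p_bigram, colloc = bs$colloc,
         priors = priors %||% tibble::tibble(method_id = character(),
                                             weight = numeric()),
         zone = zone, n_docs = nrow(docs)),
    class = "term_stats"
  )
}

#' @export
print.term_stats <- function(x, ...) {
  cat("<term_stats> fitted on ", x$n_docs, " documents (zone: ", x$zone,
      ")\n  p(method|word) entries: ", nrow(x$p_word),
      "\n  termness entries:       ", nrow(x$termness),
      "\n  p(method|bigram):       ", nrow(x$p_bigram), "\n", sep = "")
  invisible(x)
}

prior_lookup <- function(model, method_ids) {
  w <- rep(1, length(method_ids))
  if (nrow(model$priors) > 0L) {
    idx <- match(method_ids, model$priors$method_id)
    w[!is.na(idx)] <- model$priors$weight[idx[!is.na(idx)]]
  }
  w
}

# shared word-level summation: score(m, d) = prior(m) * sum over occurrences
# of p(m|w) * termness(w), over the word occurrences in `wt`
word_score_map <- function(wt, model, word_filter = NULL) {
  tab <- model$p_word
  if (!is.null(word_filter)) tab <- word_filter(tab)
  if (nrow(wt) == 0L || nrow(tab) == 0L) {
    return(tibble::tibble(doc_id = character(), method_id = character(),
                          score = numeric()))
  }
  scored <- wt |>
    dplyr::inner_join(tab, by = "word", relationship = "many-to-many") |>
    dplyr::inner_join(model$termness, by = "word") |>
    dplyr::group_by(.data$doc_id, .data$method_id) |>
    dplyr::summarise(score = sum(.data$p * .data$termness),
                     .groups = "drop")
  scored$score <- scored$score * prior_lookup(model, scored$method_id)
  dplyr::filter(scored, .data$score > 0)
}

#' Statistical-dictionary scorer
#'
#' Applies the term-statistics model to the word occurrences that are
#' matches or submatches of the dictionary terms: every occurrence of an
#' indexed word `w` contributes `p(m|w) * termness(w)` to method `m`, the
#' sum is scaled by the method's prior weight.
#'
#' @param docs documents tibble.
#' @param model fitted `term_stats` model.
#' @param index `term_index` restricting scoring to dictionary words.
#' @param zone matching zone.
#' @return score-map tibble `doc_id`, `method_id`, `score`.
#' @export
score_statistical_dictionary <- function(docs, model, index,
                                         zone = model$zone) {
  wt <- corpus_word_table(docs, zone)
  dict_words <- unique(index$words$word)
  word_score_map(wt[wt$word %in% dict_words, , drop = FALSE], model)
}

#' Corpus-driven scorer (no dictionary)
#'
#' The same summation applied to all word occurrences, restricted to words
#' whose statistics pass the reliability thresholds: `p(m|w)` above
#' `p_min`, termness above `termness_min`, and the word used in at least
#' `df_min` training documents.
#'
#' @param docs,model,zone as in [score_statistical_dictionary()].
#' @param p_min,termness_min strict lower bounds, default 0.10 ("above
#'   10%").
#' @param df_min minimum training document frequency, default 5.
#' @return score-map tibble `doc_id`, `method_id`, `score`.
#' @export
score_corpus_driven <- function(docs, model, p_min = 0.10,
                                termness_min = 0.10, df_min = 5L,
                                zone = model$zone) {
  wt <- corpus_word_table(docs, zone)
  keep_words <- model$termness$word[model$termness$termness > termness_min]
  word_score_map(
    wt[wt$word %in% keep_words, , drop = FALSE], model,
    word_filter = function(tab) {
      tab[tab$p > p_min & tab$n_docs_word >= df_min, , drop = FALSE]
    }
  )
}

#' Bigram scorer with collocation weighting
#'
#' Every adjacent bigram `b` of the document with `p(m|b)` above `p_min`
#' contributes `p(m|b) * (1 + log(1 + chi2(b)))` to method `m` (the
#' log-damped chi-square factor up-weights collocational multi-word terms);
#' with `use_colloc = FALSE` the factor is 1 and the plain bigram model is
#' recovered.
#'
#' @param docs,model,zone as above.
#' @param p_min strict lower bound on `p(method|bigram)`, default 0.10.
#' @param use_colloc apply the collocation weight factor? Default `TRUE`.
#' @return score-map tibble `doc_id`, `method_id`, `score`.
#' @export
score_bigram <- function(docs, model, p_min = 0.10, use_colloc = TRUE,
                         zone = model$zone) {
  texts <- zone_text(docs, zone)
  bt <- purrr::map2(docs$doc_id, texts, function(id, txt) {
    bg <- cm_bigrams(doc_words(txt))
    if (nrow(bg) == 0L) return(NULL)
    bg$doc_id <- id
    bg
  }) |> dplyr::bind_rows()
  tab <- model$p_bigram[model$p_bigram$p > p_min, , drop = FALSE]
  if (is.null(bt) || nrow(bt) == 0L || nrow(tab) == 0L) {
    return(tibble::tibble(doc_id = character(), method_id = character(),
                          score = numeric()))
  }
  scored <- bt |>
    dplyr::inner_join(tab, by = c("w1", "w2"),
                      relationship = "many-to-many") |>
    dplyr::left_join(model$colloc, by = c("w1", "w2")) |>
    dplyr::mutate(
      chi2 = dplyr::coalesce(.data$chi2, 0),
      contrib = if (use_colloc) {
        .data$p * (1 + log(1 + .data$chi2))
      } else {
        .data$p
      }
    ) |>
    dplyr::group_by(.data$doc_id, .data$method_id) |>
    dplyr::summarise(score = sum(.data$contrib), .groups = "drop")
  scored$score <- scored$score * prior_lookup(model, scored$method_id)
  dplyr::filter(scored, .data$score > 0)
}

#' Combine score maps additively
#'
#' Per-method elementwise sum across score maps; a method missing from a
#' map counts as 0 there.
#'
#' @param ... score-map tibbles (`doc_id`, `method_id`, `score`), or a
#'   single list of them.
#' @return combined score-map tibble.
#' @export
combine_additive <- function(...) {
  maps <- collect_maps(...)
  dplyr::bind_rows(maps) |>
    dplyr::group_by(.data$doc_id, .data$method_id) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop")
}

#' Combine score maps by averaging normalized scores
#'
#' Each map is first min-max normalized per document to \[0, 1\] (scores
#' are non-negative and an absent method reads as 0, so this is score
#' divided by the per-document maximum); the combined score is the mean of
#' the normalized scores over all maps, with absent entries contributing 0.
#'
#' @inheritParams combine_additive
#' @return combined score-map tibble with scores in \[0, 1\].
#' @export
combine_average <- function(...) {
  maps <- collect_maps(...)
  k <- length(maps)
  normed <- purrr::map(maps, function(m) {
    if (nrow(m) == 0L) return(m)
    m |>
      dplyr::group_by(.data$doc_id) |>
      dplyr::mutate(
        .max = max(.data$score),
        score = ifelse(.data$.max > 0, .data$score / .data$.max, 0)
      ) |>
      dplyr::ungroup() |>
      dplyr::select(-".max")
  })
  dplyr::bind_rows(normed) |>
    dplyr::group_by(.data$doc_id, .data$method_id) |>
    dplyr::summarise(score = sum(.data$score) / k, .groups = "drop")
}

collect_maps <- function(...) {
  maps <- list(...)
  if (length(maps) == 1L && is.list(maps[[1]]) &&
      !is.data.frame(maps[[1]])) {
    maps <- maps[[1]]
  }
  if (length(maps) == 0L) rlang::abort("no score maps supplied")
  single <- purrr::map_chr(maps, function(m) {
    ids <- unique(m$doc_id)
    if (length(ids) == 1L) ids else NA_character_
  })
  if (all(!is.na(single)) && length(unique(single)) > 1L &&
      all(purrr::map_int(maps, ~ dplyr::n_distinct(.x$doc_id)) == 1L)) {
    rlang::abort("combine: score maps refer to different doc_ids")
  }
  maps
}

#' Rank a score map into predictions
#'
#' Within each document, methods are sorted by score (descending), ties
#' broken by prior weight (descending) then method id (ascending);
#' zero-score methods are dropped. Confidence is the score divided by the
#' document's maximum score, so it is 1 at rank 1 and non-increasing.
#'
#' @param score_map tibble `doc_id`, `method_id`, `score`.
#' @param model optional `term_stats` model supplying prior weights for
#'   tie-breaking.
#' @param rank_threshold optional integer; keep only ranks up to it.
#' @return predictions tibble `doc_id`, `method_id`, `rank`, `confidence`,
#'   `score`.
#' @export
rank_predictions <- function(score_map, model = NULL,
                             rank_threshold = NULL) {
  if (!is.null(rank_threshold) && rank_threshold < 1L) {
    rlang::abort("rank_predictions(): rank_threshold must be >= 1")
  }
  out <- dplyr::filter(score_map, .data$score > 0)
  if (nrow(out) == 0L) {
    return(tibble::tibble(doc_id = character(), method_id = character(),
                          rank = integer(), confidence = numeric(),
                          score = numeric()))
  }
  out$prior <- if (!is.null(model)) {
    prior_lookup(model, out$method_id)
  } else {
    1
  }
  out <- out |>
    dplyr::arrange(.data$doc_id, dplyr::desc(.data$score),
                   dplyr::desc(.data$prior), .data$method_id) |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  confidence = .data$score / max(.data$score)) |>
    dplyr::ungroup() |>
    dplyr::select("doc_id", "method_id", "rank", "confidence", "score")
  if (!is.null(rank_threshold)) {
    out <- dplyr::filter(out, .data$rank <= rank_threshold)
  }
  out
}

#' One-call method detection in a chosen mode
#'
#' Convenience wrapper running the configured scorer(s) and ranking the
#' result. Modes: `dict` (tiered dictionary matching), `statdict`
#' (dictionary words weighted by corpus statistics), `corpus`
#' (corpus-driven, no dictionary), `bigram` (bigram + collocation model),
#' `combined` (additive combination of statdict, corpus and bigram).
#'
#' @param docs documents tibble (zoned with [detect_method_section()] when
#'   `zone = "methods"`).
#' @param model fitted `term_stats` model (not needed for `mode = "dict"`).
#' @param index `term_index` (needed for `dict` and `statdict`).
#' @param mode scoring mode, see above.
#' @param rank_threshold optional rank cut-off.
#' @param zone `"methods"` or `"all"`.
#' @param ... passed on to the underlying scorer.
#' @return predictions tibble from [rank_predictions()].
#' @export
imt_predict <- function(docs, model = NULL, index = NULL,
                        mode = c("combined", "dict", "statdict", "corpus",
                                 "bigram"),
                        rank_threshold = NULL, zone = "methods", ...) {
  mode <- match.arg(mode)
  need_model <- mode != "dict"
  if (need_model && is.null(model)) {
    rlang::abort(paste0("imt_predict(): mode '", mode, "' needs a model"))
  }
  map <- switch(
    mode,
    dict = imt_dict_score(docs, index, zone = zone, ...),
    statdict = score_statistical_dictionary(docs, model, index,
                                            zone = zone),
    corpus = score_corpus_driven(docs, model, zone = zone, ...),
    bigram = score_bigram(docs, model, zone = zone, ...),
    combined = combine_additive(
      score_statistical_dictionary(docs, model, index, zone = zone),
      score_corpus_driven(docs, model, zone = zone),
      score_bigram(docs, model, zone = zone)
    )
  )
  rank_predictions(map, model = model, rank_threshold = rank_threshold)
}
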
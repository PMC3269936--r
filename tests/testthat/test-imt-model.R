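# All documents in these fixtures are built without section headings, so
# zoning falls back to the whole body; zone = "all" style counting is then
# exercised explicitly where relevant.

mk_idx_one <- function(id, term) {
  ont <- tibble::tibble(method_id = id, name = term,
                        synonyms = list(character()))
  build_term_index(ont)
}

imt_fixture <- function() {
  docs <- detect_method_section(toy_docs(c(
    "purification purification assay",   # d1
    "purification control sample",       # d2
    "binding assay control"              # d3
  )))
  gold <- tibble::tibble(doc_id = c("d1", "d3"),
                         method_id = c("MI:0004", "MI:0006"))
  ont <- toy_ontology(
    "MI:0004" = c("affinity chromatography technology",
                  "affinity purification"),
    "MI:0006" = "anti bait coip"
  )
  list(docs = docs, gold = gold, ont = ont)
}

test_that("p(method|word) counts documents, stores only seen pairs", {
  fx <- imt_fixture()
  tab <- estimate_method_given_word(fx$docs, fx$gold)
  # "purification" occurs in d1 (gold MI:0004) and d2 (no gold) -> 1/2
  expect_equal(tab$p[tab$word == "purification" &
                       tab$method_id == "MI:0004"], 0.5)
  # "assay" occurs in d1 (MI:0004) and d3 (MI:0006) -> both 1/2
  expect_equal(sort(tab$method_id[tab$word == "assay"]),
               c("MI:0004", "MI:0006"))
  expect_equal(tab$p[tab$word == "assay"], c(0.5, 0.5))
  # "binding" only in d3 -> p(MI:0006 | binding) = 1
  expect_equal(tab$p[tab$word == "binding"], 1)
  # unseen pairs are simply absent
  expect_false(any(tab$word == "purification" & tab$method_id == "MI:0006"))
})

test_that("multi-label documents make p(m|w) sum above 1", {
  docs <- detect_method_section(toy_docs("shared word here"))
  gold <- tibble::tibble(doc_id = c("d1", "d1"),
                         method_id = c("M1", "M2"))
  tab <- estimate_method_given_word(docs, gold)
  sums <- tapply(tab$p, tab$word, sum)
  expect_true(all(sums == 2))
})

test_that("termness counts token occurrences in term-covered documents", {
  fx <- imt_fixture()
  tn <- estimate_termness(fx$docs, fx$gold, fx$ont)
  # "purification": 2 occurrences in d1 (gold MI:0004, whose synonym
  # contains the word) + 1 in d2 (no gold) -> 2/3
  expect_equal(tn$termness[tn$word == "purification"], 2 / 3)
  # "control" is in no method term -> termness 0 despite gold on d3
  expect_equal(tn$termness[tn$word == "control"], 0)
  # "anti" never occurs in the corpus -> no row, lookups read as 0
  expect_false("anti" %in% tn$word)
})

test_that("probability tables equal naive recounts on generated corpora", {
  spec <- fixture_spec(seed = 31, n_methods = 5, n_docs = 10,
                       doc_length = c(15, 30), plant_rate = 0.6)
  ont <- gen_ontology(spec)
  corp <- gen_imt_corpus(ont, spec)
  got_p <- estimate_method_given_word(corp$docs, corp$gold) |>
    dplyr::arrange(method_id, word)
  want_p <- oracle_p_word(corp$docs, corp$gold) |>
    dplyr::arrange(method_id, word)
  expect_equal(got_p, want_p)

  got_t <- estimate_termness(corp$docs, corp$gold, ont) |>
    dplyr::arrange(word)
  want_t <- oracle_termness(corp$docs, corp$gold, ont) |>
    dplyr::arrange(word)
  expect_equal(got_t$word, want_t$word)
  expect_equal(got_t$termness, want_t$termness)
})

test_that("bigram probabilities and chi-square collocation are correct", {
  docs <- detect_method_section(toy_docs(c(
    "yeast two-hybrid assay works",
    "yeast two-hybrid again",
    "random words here"
  )))
  gold <- tibble::tibble(doc_id = c("d1", "d2"),
                         method_id = c("M1", "M1"))
  bs <- estimate_bigram_stats(docs, gold)
  # "yeast two-hybrid" occurs only in M1-annotated documents -> p = 1
  row <- bs$p_bigram[bs$p_bigram$w1 == "yeast", ]
  expect_equal(row$p, 1)
  expect_equal(row$method_id, "M1")

  # direct formula on a fixed 2x2 table is the oracle
  o <- c(8, 2, 2, 88)
  e <- outer(c(o[1] + o[2], o[3] + o[4]), c(o[1] + o[3], o[2] + o[4])) /
    sum(o)
  expect_equal(chi_square_2x2(o[1], o[2], o[3], o[4]),
               sum((matrix(o, 2, byrow = TRUE) - e)^2 / e))
  # and agrees with the standard implementation, uncorrected
  expect_equal(
    chi_square_2x2(o[1], o[2], o[3], o[4]),
    unname(suppressWarnings(stats::chisq.test(
      matrix(o, 2, byrow = TRUE), correct = FALSE))$statistic)
  )
  # observed = expected -> 0
  expect_equal(chi_square_2x2(10, 10, 10, 10), 0)
})

test_that("prior adjustment floors development precision", {
  tab <- tibble::tibble(method_id = c("M1", "M2"), precision = c(0, 0.8))
  pr <- adjust_priors(tab)
  expect_equal(pr$weight[pr$method_id == "M1"], 0.05)
  expect_equal(pr$weight[pr$method_id == "M2"], 0.8)
  expect_error(adjust_priors(tibble::tibble(method_id = "M",
                                            precision = 1.2)),
               "\\[0, 1\\]")
})

test_that("statistical-dictionary scoring is the prior-weighted product sum", {
  docs <- detect_method_section(toy_docs("purification"))
  model <- structure(list(
    p_word = tibble::tibble(method_id = "M1", word = "purification",
                            p = 0.5, n_docs_word = 10L),
    termness = tibble::tibble(word = "purification", termness = 0.6,
                              n_occ = 10L),
    p_bigram = tibble::tibble(method_id = character(), w1 = character(),
                              w2 = character(), p = numeric()),
    colloc = tibble::tibble(w1 = character(), w2 = character(),
                            chi2 = numeric()),
    priors = tibble::tibble(method_id = character(), weight = numeric()),
    zone = "methods", n_docs = 10L
  ), class = "term_stats")
  idx <- mk_idx_one("M1", "affinity purification")
  sc <- score_statistical_dictionary(docs, model, idx)
  expect_equal(sc$score, 0.5 * 0.6)

  # no indexed words -> empty map
  docs2 <- detect_method_section(toy_docs("nothing relevant"))
  expect_equal(nrow(score_statistical_dictionary(docs2, model, idx)), 0L)

  # doubling every token doubles every score (linearity)
  docs3 <- detect_method_section(toy_docs("purification purification"))
  sc3 <- score_statistical_dictionary(docs3, model, idx)
  expect_equal(sc3$score, 2 * sc$score)

  # prior weight scales the score
  model$priors <- tibble::tibble(method_id = "M1", weight = 0.2)
  expect_equal(score_statistical_dictionary(docs, model, idx)$score,
               0.2 * 0.5 * 0.6)
})

test_that("corpus-driven scoring enforces its reliability thresholds", {
  mk_model <- function(p, termness, df) {
    structure(list(
      p_word = tibble::tibble(method_id = "M1", word = "w", p = p,
                              n_docs_word = as.integer(df)),
      termness = tibble::tibble(word = "w", termness = termness,
                                n_occ = 10L),
      p_bigram = tibble::tibble(method_id = character(), w1 = character(),
                                w2 = character(), p = numeric()),
      colloc = tibble::tibble(w1 = character(), w2 = character(),
                              chi2 = numeric()),
      priors = tibble::tibble(method_id = character(), weight = numeric()),
      zone = "methods", n_docs = 20L
    ), class = "term_stats")
  }
  docs <- detect_method_section(toy_docs("w"))
  # p below the 10% threshold contributes nothing
  expect_equal(nrow(score_corpus_driven(docs, mk_model(0.09, 0.8, 10))), 0L)
  # document frequency below 5 contributes nothing
  expect_equal(nrow(score_corpus_driven(docs, mk_model(0.4, 0.8, 4))), 0L)
  # termness below threshold contributes nothing
  expect_equal(nrow(score_corpus_driven(docs, mk_model(0.4, 0.1, 10))), 0L)
  # all thresholds passed: p * termness per occurrence
  expect_equal(score_corpus_driven(docs, mk_model(0.4, 0.8, 10))$score,
               0.32)
  # thresholds are strict for p/termness, inclusive for df
  expect_equal(nrow(score_corpus_driven(docs, mk_model(0.1, 0.8, 5))), 0L)
  expect_equal(score_corpus_driven(docs, mk_model(0.11, 0.8, 5))$score,
               0.11 * 0.8)
})

test_that("raising corpus-driven thresholds never increases scores", {
  spec <- fixture_spec(seed = 37, n_methods = 4, n_docs = 30,
                       plant_rate = 0.7)
  ont <- gen_ontology(spec)
  corp <- gen_imt_corpus(ont, spec)
  model <- term_stats_fit(corp$docs, corp$gold, ont)
  base <- score_corpus_driven(corp$docs, model, p_min = 0.1,
                              termness_min = 0.1, df_min = 5)
  for (args in list(list(p_min = 0.3), list(termness_min = 0.3),
                    list(df_min = 8))) {
    tighter <- do.call(score_corpus_driven,
                       c(list(corp$docs, model), args))
    j <- dplyr::left_join(tighter, base,
                          by = c("doc_id", "method_id"),
                          suffix = c("_tight", "_base"))
    expect_true(all(j$score_tight <= j$score_base + 1e-12))
  }
})

test_that("bigram scoring applies the collocation factor per occurrence", {
  mk_model <- function(p, chi2) {
    structure(list(
      p_word = tibble::tibble(method_id = character(), word = character(),
                              p = numeric(), n_docs_word = integer()),
      termness = tibble::tibble(word = character(), termness = numeric(),
                                n_occ = integer()),
      p_bigram = tibble::tibble(method_id = "M1", w1 = "two-hybrid",
                                w2 = "assay", p = p),
      colloc = tibble::tibble(w1 = "two-hybrid", w2 = "assay", chi2 = chi2),
      priors = tibble::tibble(method_id = character(), weight = numeric()),
      zone = "methods", n_docs = 20L
    ), class = "term_stats")
  }
  docs <- detect_method_section(toy_docs("two-hybrid assay"))
  # zero collocation weight: factor (1 + log(1 + 0)) = 1
  expect_equal(score_bigram(docs, mk_model(0.5, 0))$score, 0.5)
  # below the probability threshold -> nothing
  expect_equal(nrow(score_bigram(docs, mk_model(0.09, 5))), 0L)
  # two occurrences double the score
  docs2 <- detect_method_section(
    toy_docs("two-hybrid assay and two-hybrid assay"))
  m <- mk_model(0.5, 3)
  expect_equal(score_bigram(docs2, m)$score, 2 * score_bigram(docs, m)$score)
  # collocation factor off reproduces the plain bigram model
  expect_equal(score_bigram(docs, mk_model(0.5, 3), use_colloc = FALSE)$score,
               0.5)
  expect_equal(score_bigram(docs, mk_model(0.5, 3))$score,
               0.5 * (1 + log(4)))
})

test_that("additive and averaging combination behave as stated", {
  m1 <- tibble::tibble(doc_id = "d", method_id = "M1", score = 0.3)
  m2 <- tibble::tibble(doc_id = "d", method_id = c("M1", "M2"),
                       score = c(0.2, 0.1))
  add <- combine_additive(m1, m2) |> dplyr::arrange(method_id)
  expect_equal(add$score, c(0.5, 0.1))
  # identity and commutativity
  empty <- tibble::tibble(doc_id = character(), method_id = character(),
                          score = numeric())
  expect_equal(combine_additive(m1, empty), m1)
  expect_equal(combine_additive(m1, m2), combine_additive(m2, m1))
  expect_error(combine_additive(
    m1, tibble::tibble(doc_id = "other", method_id = "M1", score = 1)
  ), "different doc_ids")

  a <- tibble::tibble(doc_id = "d", method_id = "M1", score = 1.0)
  b <- tibble::tibble(doc_id = "d", method_id = c("M1", "M2"),
                      score = c(0.0, 1.0))
  avg <- combine_average(a, b) |> dplyr::arrange(method_id)
  expect_equal(avg$score, c(0.5, 0.5))
  # idempotence on a single map
  self <- combine_average(m2, m2) |> dplyr::arrange(method_id)
  expect_equal(self$score, c(1.0, 0.5))  # min-max normalized copy of m2
  expect_true(all(avg$score >= 0 & avg$score <= 1))
})

test_that("ranking sorts, normalizes confidence and honours the threshold", {
  map <- tibble::tibble(doc_id = "d", method_id = c("M1", "M2"),
                        score = c(2, 1))
  pr <- rank_predictions(map)
  expect_equal(pr$method_id, c("M1", "M2"))
  expect_equal(pr$rank, c(1L, 2L))
  expect_equal(pr$confidence, c(1, 0.5))

  pr1 <- rank_predictions(map, rank_threshold = 1)
  expect_equal(pr1$method_id, "M1")
  # thresholded output is a prefix of the full ranking
  expect_equal(pr1, pr[1, ])

  expect_equal(nrow(rank_predictions(
    tibble::tibble(doc_id = character(), method_id = character(),
                   score = numeric()))), 0L)
  # zero scores are dropped
  map0 <- tibble::tibble(doc_id = "d", method_id = c("M1", "M2"),
                         score = c(1, 0))
  expect_equal(rank_predictions(map0)$method_id, "M1")
  expect_error(rank_predictions(map, rank_threshold = 0), ">= 1")
})

test_that("confidences are in (0,1] and non-increasing within documents", {
  spec <- fixture_spec(seed = 41, n_methods = 5, n_docs = 20,
                       plant_rate = 0.8)
  ont <- gen_ontology(spec)
  corp <- gen_imt_corpus(ont, spec)
  model <- term_stats_fit(corp$docs, corp$gold, ont)
  pr <- imt_predict(corp$docs, model, build_term_index(ont),
                    mode = "combined")
  expect_true(all(pr$confidence > 0 & pr$confidence <= 1))
  drops <- pr |>
    dplyr::group_by(doc_id) |>
    dplyr::summarise(ok = all(diff(confidence) <= 1e-12),
                     first = confidence[rank == 1])
  expect_true(all(drops$ok))
  expect_true(all(drops$first == 1))
})

test_that("documents planting one method's vocabulary rank it first", {
  spec <- fixture_spec(seed = 43, n_methods = 6, n_docs = 80,
                       plant_rate = 1, noise_overlap = 0,
                       methods_per_doc = c(1, 1))
  ont <- gen_ontology(spec)
  corp <- gen_imt_corpus(ont, spec)
  model <- term_stats_fit(corp$docs, corp$gold, ont)
  pr <- imt_predict(corp$docs, model, build_term_index(ont),
                    mode = "corpus")
  top1 <- pr |>
    dplyr::filter(rank == 1) |>
    dplyr::inner_join(corp$gold, by = c("doc_id", "method_id"))
  expect_gte(nrow(top1) / dplyr::n_distinct(corp$gold$doc_id), 0.9)
})

test_that("scorers return nothing on text-free documents", {
  spec <- fixture_spec(seed = 47, n_methods = 3, n_docs = 10)
  ont <- gen_ontology(spec)
  corp <- gen_imt_corpus(ont, spec)
  model <- term_stats_fit(corp$docs, corp$gold, ont)
  empty <- detect_method_section(toy_docs("x\n", ids = "empty1"))
  expect_equal(nrow(score_corpus_driven(empty, model)), 0L)
  expect_equal(nrow(score_bigram(empty, model)), 0L)
})
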
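# Seeded synthetic-data generators: method ontologies with controllable
# vocabulary overlap, method-detection corpora with planted signal
# vocabulary and a methods-like section, and article-classification corpora
# with a 17% positive rate (the class-1 fraction of the task's development
# set). Every generator is a pure function of its FixtureSpec.

#' Specification for the synthetic generators
#'
#' @param seed integer master seed; every generator derives its stream
#'   from it, so identical specs give byte-identical outputs.
#' @param n_methods number of methods in the ontology.
#' @param vocab_size size of the Zipf-distributed background vocabulary.
#' @param n_docs number of documents per generated corpus.
#' @param doc_length inclusive range of document token counts.
#' @param methods_per_doc inclusive range of gold methods per document.
#' @param plant_rate probability that a token of a document is drawn from
#'   an assigned method's signal vocabulary rather than the background.
#' @param noise_overlap probability that a signal word of a method term is
#'   drawn from a pool shared between methods rather than the method's
#'   private pool.
#' @param act_positive_fraction fraction of curatable (class 1) articles,
#'   default 0.17.
#' @param act_signal_strength probability that a positive article receives
#'   each interaction-signal word / MeSH descriptor.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_methods = 10L, vocab_size = 200L,
                         n_docs = 100L, doc_length = c(40L, 80L),
                         methods_per_doc = c(1L, 3L), plant_rate = 0.5,
                         noise_overlap = 0, act_positive_fraction = 0.17,
                         act_signal_strength = 0.8) {
  probs <- c(plant_rate, noise_overlap, act_positive_fraction,
             act_signal_strength)
  stopifnot(all(probs >= 0 & probs <= 1), n_methods >= 1L, n_docs >= 1L,
            vocab_size >= 1L, doc_length[1] >= 1L,
            doc_length[2] >= doc_length[1])
  structure(
    list(seed = as.integer(seed), n_methods = as.integer(n_methods),
         vocab_size = as.integer(vocab_size), n_docs = as.integer(n_docs),
         doc_length = as.integer(doc_length),
         methods_per_doc = as.integer(methods_per_doc),
         plant_rate = plant_rate, noise_overlap = noise_overlap,
         act_positive_fraction = act_positive_fraction,
         act_signal_strength = act_signal_strength),
    class = "fixture_spec"
  )
}

# private signal vocabulary per method + one shared pool
signal_pools <- function(spec, words_per_method = 8L) {
  list(
    private = lapply(seq_len(spec$n_methods), function(i) {
      sprintf("methword%02d%02d", i, seq_len(words_per_method))
    }),
    shared = sprintf("sharedword%02d", seq_len(words_per_method))
  )
}

#' Generate a synthetic method ontology
#'
#' Each method gets a term of 1-4 words plus 0-2 synonyms of 1-3 words,
#' drawn from its private signal vocabulary, or (with probability
#' `noise_overlap`) from a pool shared between all methods. With
#' `noise_overlap = 0` the methods' vocabularies are disjoint; with 1 they
#' coincide.
#'
#' @param spec a [fixture_spec()].
#' @return an ontology tibble (`method_id`, `name`, `synonyms`).
#' @export
gen_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  pools <- signal_pools(spec)
  if (spec$n_methods > 99L) {
    rlang::abort("gen_ontology(): at most 99 methods supported")
  }
  with_seed_restore(spec$seed, {
    entries <- purrr::map(seq_len(spec$n_methods), function(i) {
      draw_words <- function(k) {
        vapply(seq_len(k), function(j) {
          if (stats::runif(1) < spec$noise_overlap) {
            sample(pools$shared, 1L)
          } else {
            sample(pools$private[[i]], 1L)
          }
        }, character(1))
      }
      name <- paste(unique(draw_words(sample(1:4, 1L))), collapse = " ")
      n_syn <- sample(0:2, 1L)
      syns <- vapply(seq_len(n_syn), function(s) {
        paste(unique(draw_words(sample(1:3, 1L))), collapse = " ")
      }, character(1))
      tibble::tibble(method_id = sprintf("MI:%04d", i),
                     name = name, synonyms = list(unique(syns)))
    })
    dplyr::bind_rows(entries)
  })
}

# Zipf-distributed background word sampler
background_sampler <- function(spec) {
  words <- sprintf("bgword%04d", seq_len(spec$vocab_size))
  probs <- 1 / seq_len(spec$vocab_size)
  probs <- probs / sum(probs)
  function(k) sample(words, k, replace = TRUE, prob = probs)
}

ontology_word_pool <- function(ontology) {
  lapply(seq_len(nrow(ontology)), function(i) {
    unique(unlist(lapply(
      c(ontology$name[i], ontology$synonyms[[i]]),
      function(s) strsplit(s, " ", fixed = TRUE)[[1]]
    )))
  })
}

#' Generate a method-detection corpus with planted signal words
#'
#' Every document is assigned gold methods; each token of its methods
#' section is drawn from the assigned methods' term vocabulary with
#' probability `plant_rate`, otherwise from the Zipf background. The body
#' carries an introduction, a "Methods" heading and a closing "Results"
#' heading so zoning is exercised. Gold annotations are document-level
#' only, mirroring the training material of the task (which gives the
#' methods of each document but not their positions).
#'
#' @param ontology ontology tibble (normally from [gen_ontology()]).
#' @param spec a [fixture_spec()].
#' @return `list(docs = documents tibble, gold = tibble(doc_id,
#'   method_id))`.
#' @export
gen_imt_corpus <- function(ontology, spec) {
  stopifnot(inherits(spec, "fixture_spec"), nrow(ontology) >= 1L)
  pools <- ontology_word_pool(ontology)
  bg <- background_sampler(spec)
  with_seed_restore(spec$seed + 1L, {
    rows <- purrr::map(seq_len(spec$n_docs), function(d) {
      id <- sprintf("doc%04d", d)
      k <- sample(seq(spec$methods_per_doc[1],
                      min(spec$methods_per_doc[2], nrow(ontology))), 1L)
      gold_idx <- sample(nrow(ontology), k)
      signal <- unique(unlist(pools[gold_idx]))
      len <- sample(seq(spec$doc_length[1], spec$doc_length[2]), 1L)
      plant <- stats::runif(len) < spec$plant_rate
      toks <- character(len)
      toks[plant] <- sample(signal, sum(plant), replace = TRUE)
      toks[!plant] <- bg(sum(!plant))
      body <- paste0(
        "Introduction\n", paste(bg(8L), collapse = " "), "\n",
        "Methods\n", paste(toks, collapse = " "), "\n",
        "Results\n", paste(bg(5L), collapse = " ")
      )
      list(
        doc = tibble::tibble(
          doc_id = id, title = paste(bg(4L), collapse = " "), body = body,
          mesh = list(character()), method_start = NA_integer_,
          method_end = NA_integer_, zoning_fallback = NA
        ),
        gold = tibble::tibble(doc_id = id,
                              method_id = ontology$method_id[gold_idx])
      )
    })
    docs <- dplyr::bind_rows(purrr::map(rows, "doc"))
    gold <- dplyr::bind_rows(purrr::map(rows, "gold"))
    list(docs = detect_method_section(docs), gold = gold)
  })
}

# interaction-signal vocabulary for curatable articles
act_signal_words <- c(
  "interacts", "interaction", "binds", "binding", "complex",
  "coimmunoprecipitation", "two-hybrid", "pulldown", "crosslinking",
  "heterodimer"
)
act_signal_mesh <- c(
  "-Protein Interaction Mapping (+methods)",
  "-Two-Hybrid System Techniques",
  "-Protein Binding (+physiology)",
  "-Immunoprecipitation (+methods)"
)
act_background_mesh <- c(
  "-Humans", "-Animals", "-Mice", "-Cell Line",
  "-Signal Transduction (-drug effects; +physiology)",
  "-Apoptosis (+genetics)", "-Gene Expression Regulation"
)

#' Generate an article-classification corpus
#'
#' `round(n_docs * act_positive_fraction)` documents are curatable
#' (label 1): each receives every interaction-signal word and each signal
#' MeSH descriptor independently with probability `act_signal_strength`,
#' on top of Zipf background text shared with the negatives. With
#' `act_signal_strength = 0` the classes are indistinguishable.
#'
#' @param spec a [fixture_spec()].
#' @return `list(docs = documents tibble with MeSH lines, gold =
#'   tibble(doc_id, label))`.
#' @export
gen_act_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"), spec$n_docs >= 20L)
  bg <- background_sampler(spec)
  n_pos <- round(spec$n_docs * spec$act_positive_fraction)
  with_seed_restore(spec$seed + 2L, {
    labels <- c(rep(1L, n_pos), rep(0L, spec$n_docs - n_pos))
    rows <- purrr::map(seq_len(spec$n_docs), function(d) {
      id <- sprintf("act%04d", d)
      len <- sample(seq(spec$doc_length[1], spec$doc_length[2]), 1L)
      toks <- bg(len)
      mesh <- sample(act_background_mesh,
                     sample(1:3, 1L), replace = FALSE)
      if (labels[d] == 1L) {
        take <- stats::runif(length(act_signal_words)) <
          spec$act_signal_strength
        toks <- c(toks, act_signal_words[take])
        toks <- sample(toks)  # shuffle signal into the text
        mtake <- stats::runif(length(act_signal_mesh)) <
          spec$act_signal_strength
        mesh <- c(mesh, act_signal_mesh[mtake])
      }
      tibble::tibble(
        doc_id = id, title = paste(bg(5L), collapse = " "),
        body = paste(toks, collapse = " "), mesh = list(mesh),
        method_start = NA_integer_, method_end = NA_integer_,
        zoning_fallback = NA
      )
    })
    list(
      docs = dplyr::bind_rows(rows),
      gold = tibble::tibble(doc_id = sprintf("act%04d",
                                             seq_len(spec$n_docs)),
                            label = labels)
    )
  })
}
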
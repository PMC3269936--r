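# Dictionary-based detection of experimental methods: inverted word index
# over PSI-MI terms/synonyms, full / subset-in-window / single-word
# submatches, and tiered scoring.

#' Build an inverted word index over a method ontology
#'
#' Every term name and synonym is lowercased and word-split; after removing
#' the stopwords (by default only the prepositions "of" and "in", which
#' occur in many method terms), each remaining word maps to the methods
#' whose terms contain it. The full word sequences are kept for exact
#' matching, and the distinct content words per term for subset matching.
#'
#' @param ontology ontology tibble (`method_id`, `name`, `synonyms`).
#' @param stopwords words excluded from the index; default `c("of", "in")`.
#' @param extra_synonyms optional tibble (`method_id`, `synonym`) of
#'   user-supplied additional terminology merged in before indexing.
#' @return an object of class `term_index`: list with `words` (tibble
#'   `word`, `method_id`), `terms` (tibble `term_id`, `method_id`, `words`
#'   list-column, `content_words` list-column) and `stopwords`.
#' @export
build_term_index <- function(ontology, stopwords = c("of", "in"),
                             extra_synonyms = NULL) {
  if (nrow(ontology) == 0L) {
    rlang::abort("build_term_index(): empty ontology")
  }
  strings <- purrr::pmap(
    list(ontology$method_id, ontology$name, ontology$synonyms),
    function(id, name, syns) {
      tibble::tibble(method_id = id, string = c(name, syns))
    }
  )
  strings <- dplyr::bind_rows(strings)
  if (!is.null(extra_synonyms) && nrow(extra_synonyms) > 0L) {
    strings <- dplyr::bind_rows(
      strings,
      tibble::tibble(method_id = extra_synonyms$method_id,
                     string = extra_synonyms$synonym)
    )
  }
  stopwords <- tolower(stopwords)
  terms <- strings |>
    dplyr::mutate(
      term_id = dplyr::row_number(),
      words = purrr::map(.data$string, function(s) {
        w <- tolower(cm_tokenize(s, stem_tokens = FALSE)$surface)
        w[nzchar(w)]
      }),
      content_words = purrr::map(.data$words, function(w) {
        unique(setdiff(w, stopwords))
      })
    ) |>
    dplyr::filter(lengths(.data$words) > 0L) |>
    dplyr::select("term_id", "method_id", "string", "words", "content_words")
  words <- terms |>
    dplyr::select("method_id", "content_words") |>
    tidyr::unnest_longer("content_words", values_to = "word") |>
    dplyr::distinct(.data$word, .data$method_id)
  structure(
    list(words = words, terms = terms, stopwords = stopwords),
    class = "term_index"
  )
}

#' @export
print.term_index <- function(x, ...) {
  cat("<term_index> ", dplyr::n_distinct(x$terms$method_id), " methods, ",
      nrow(x$terms), " term strings, ", nrow(x$words),
      " word-method index entries\n", sep = "")
  invisible(x)
}

#' Find dictionary matches in a token sequence
#'
#' Emits three kinds of match events against a [build_term_index()] index:
#' `full` for every contiguous occurrence of a complete term or synonym;
#' `subset` when at least `subset_min` distinct content words of one term
#' co-occur inside a sliding observation window of `window` tokens
#' (overlapping windows that capture the same word occurrences are merged
#' into one event); `submatch` for every occurrence of any single indexed
#' word. Submatch events whose token lies inside a full match of the same
#' method are suppressed. Matching is case-insensitive on surface forms.
#'
#' @param tokens token tibble from [cm_tokenize()].
#' @param index a `term_index`.
#' @param window observation window size in tokens (default 10).
#' @param subset_min minimum distinct term words in the window (default 4,
#'   i.e. "more than three").
#' @return a tibble with columns `method_id`, `kind`
#'   (`full`/`subset`/`submatch`), `position` (0-based token index of the
#'   first matched token), `matched_words` (list-column).
#' @export
find_matches <- function(tokens, index, window = 10L, subset_min = 4L) {
  stopifnot(inherits(index, "term_index"), window >= 1L)
  n <- nrow(tokens)
  events <- list()
  if (n == 0L) return(empty_match_events())
  words <- tolower(tokens$surface)

  # full matches: contiguous occurrence of a complete term word sequence
  full_cover <- list()  # method_id -> covered token positions (1-based)
  for (t in seq_len(nrow(index$terms))) {
    seqw <- index$terms$words[[t]]
    L <- length(seqw)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (all(words[s:(s + L - 1L)] == seqw)) {
        m <- index$terms$method_id[t]
        events[[length(events) + 1L]] <- tibble::tibble(
          method_id = m, kind = "full", position = s - 1L,
          matched_words = list(seqw)
        )
        full_cover[[m]] <- union(full_cover[[m]], s:(s + L - 1L))
      }
    }
  }

  # subset matches: >= subset_min distinct content words in a sliding window
  for (t in seq_len(nrow(index$terms))) {
    cw <- index$terms$content_words[[t]]
    if (length(cw) < subset_min) next
    hit_pos <- which(words %in% cw)
    if (length(hit_pos) == 0L) next
    seen <- character()
    for (s in seq_len(max(1L, n - window + 1L))) {
      win <- hit_pos[hit_pos >= s & hit_pos <= min(n, s + window - 1L)]
      if (length(unique(words[win])) >= subset_min) {
        key <- paste(win, collapse = ",")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          events[[length(events) + 1L]] <- tibble::tibble(
            method_id = index$terms$method_id[t], kind = "subset",
            position = win[1] - 1L,
            matched_words = list(unique(words[win]))
          )
        }
      }
    }
  }

  # submatches: every occurrence of any indexed word, minus tokens covered
  # by a full match of the same method
  idx_words <- index$words
  hits <- which(words %in% idx_words$word)
  for (s in hits) {
    mids <- idx_words$method_id[idx_words$word == words[s]]
    for (m in mids) {
      if (!is.null(full_cover[[m]]) && s %in% full_cover[[m]]) next
      events[[length(events) + 1L]] <- tibble::tibble(
        method_id = m, kind = "submatch", position = s - 1L,
        matched_words = list(words[s])
      )
    }
  }
  if (length(events) == 0L) return(empty_match_events())
  dplyr::arrange(dplyr::bind_rows(events), .data$position, .data$method_id,
                 .data$kind)
}

empty_match_events <- function() {
  tibble::tibble(method_id = character(), kind = character(),
                 position = integer(), matched_words = list())
}

#' Score match events into a per-method score map
#'
#' Every event contributes the weight of its kind; a method's score is the
#' sum over its events. Weights must respect the tier ordering
#' full > subset > submatch > 0.
#'
#' @param events match events from [find_matches()] (optionally carrying a
#'   `doc_id` column, which is preserved in the output).
#' @param weights named numeric vector with entries `full`, `subset`,
#'   `submatch`.
#' @return a score-map tibble: `method_id`, `score` (plus `doc_id` when the
#'   events carried one).
#' @export
dict_score <- function(events,
                       weights = c(full = 1.0, subset = 0.5, submatch = 0.1)) {
  w <- weights[c("full", "subset", "submatch")]
  if (anyNA(w) || !(w[1] > w[2] && w[2] > w[3] && w[3] > 0)) {
    rlang::abort("dict_score(): weights must satisfy full > subset > submatch > 0")
  }
  if (nrow(events) == 0L) {
    out <- tibble::tibble(method_id = character(), score = numeric())
    if ("doc_id" %in% names(events)) {
      out <- tibble::tibble(doc_id = character(), method_id = character(),
                            score = numeric())
    }
    return(out)
  }
  events$score <- unname(w[events$kind])
  keys <- intersect(c("doc_id", "method_id"), names(events))
  events |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(score = sum(.data$score), .groups = "drop")
}

#' Dictionary-only method detection over a document collection
#'
#' Tokenizes the matching zone of each document (the detected methods
#' section by default), finds dictionary matches and scores them.
#'
#' @param docs documents tibble (run [detect_method_section()] first when
#'   `zone = "methods"`).
#' @param index a `term_index`.
#' @param zone `"methods"` (default) or `"all"` for whole-article matching.
#' @param weights,window,subset_min passed to [dict_score()] /
#'   [find_matches()].
#' @return score-map tibble `doc_id`, `method_id`, `score`.
#' @export
imt_dict_score <- function(docs, index, zone = c("methods", "all"),
                           weights = c(full = 1.0, subset = 0.5,
                                       submatch = 0.1),
                           window = 10L, subset_min = 4L) {
  zone <- match.arg(zone)
  texts <- zone_text(docs, zone)
  maps <- purrr::map2(docs$doc_id, texts, function(id, txt) {
    ev <- find_matches(cm_tokenize(txt, stem_tokens = FALSE), index,
                       window = window, subset_min = subset_min)
    if (nrow(ev) == 0L) return(NULL)
    ev$doc_id <- id
    dict_score(ev, weights)
  })
  out <- dplyr::bind_rows(maps)
  if (nrow(out) == 0L) {
    return(tibble::tibble(doc_id = character(), method_id = character(),
                          score = numeric()))
  }
  out[, c("doc_id", "method_id", "score")]
}
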
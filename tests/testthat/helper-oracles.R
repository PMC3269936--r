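# Shared builders and independent brute-force oracles used across the
# test files. The oracles deliberately re-derive quantities with naive
# nested loops so they stay independent of the package's vectorised paths.

toy_docs <- function(bodies, titles = NULL, mesh = NULL, ids = NULL) {
  n <- length(bodies)
  tibble::tibble(
    doc_id = ids %||% paste0("d", seq_len(n)),
    title = titles %||% rep("", n),
    body = bodies,
    mesh = mesh %||% rep(list(character()), n),
    method_start = NA_integer_, method_end = NA_integer_,
    zoning_fallback = NA
  )
}

toy_ontology <- function(...) {
  entries <- list(...)
  tibble::tibble(
    method_id = names(entries),
    name = purrr::map_chr(entries, 1),
    synonyms = purrr::map(entries, function(e) {
      if (length(e) > 1) e[-1] else character()
    })
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# naive document-level recount of p(method|word)
oracle_p_word <- function(docs, gold, zone = "methods") {
  words_of <- function(i) {
    txt <- if (zone == "methods" && !is.na(docs$method_start[i])) {
      substr(docs$body[i], docs$method_start[i] + 1, docs$method_end[i])
    } else if (zone == "all") {
      paste(docs$title[i], docs$body[i])
    } else {
      docs$body[i]
    }
    unique(tolower(cm_tokenize(txt, stem_tokens = FALSE)$surface))
  }
  doc_sets <- lapply(seq_len(nrow(docs)), words_of)
  all_words <- unique(unlist(doc_sets))
  out <- list()
  for (w in all_words) {
    has_w <- which(vapply(doc_sets, function(s) w %in% s, logical(1)))
    for (m in unique(gold$method_id)) {
      m_docs <- gold$doc_id[gold$method_id == m]
      joint <- sum(docs$doc_id[has_w] %in% m_docs)
      if (joint >= 1) {
        out[[length(out) + 1]] <- tibble::tibble(
          method_id = m, word = w, p = joint / length(has_w),
          n_docs_word = length(has_w)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# naive token-level recount of termness
oracle_termness <- function(docs, gold, ontology, zone = "methods") {
  tokens_of <- function(i) {
    txt <- if (zone == "methods" && !is.na(docs$method_start[i])) {
      substr(docs$body[i], docs$method_start[i] + 1, docs$method_end[i])
    } else {
      docs$body[i]
    }
    tolower(cm_tokenize(txt, stem_tokens = FALSE)$surface)
  }
  method_words <- lapply(seq_len(nrow(ontology)), function(i) {
    unique(unlist(lapply(
      c(ontology$name[i], ontology$synonyms[[i]]),
      function(s) tolower(cm_tokenize(s, stem_tokens = FALSE)$surface)
    )))
  })
  names(method_words) <- ontology$method_id
  doc_toks <- lapply(seq_len(nrow(docs)), tokens_of)
  all_words <- unique(unlist(doc_toks))
  out <- list()
  for (w in all_words) {
    total <- 0; term <- 0
    for (i in seq_len(nrow(docs))) {
      occ <- sum(doc_toks[[i]] == w)
      total <- total + occ
      gm <- gold$method_id[gold$doc_id == docs$doc_id[i]]
      covered <- any(vapply(gm, function(m) {
        w %in% (method_words[[m]] %||% character())
      }, logical(1)))
      if (covered) term <- term + occ
    }
    out[[length(out) + 1]] <- tibble::tibble(word = w,
                                             termness = term / total,
                                             n_occ = total)
  }
  dplyr::bind_rows(out)
}

# brute-force enumeration of dictionary match events over all
# (position, term) pairs, per the stated matching rules
oracle_find_matches <- function(words, index, window = 10, subset_min = 4) {
  n <- length(words)
  events <- list()
  full_cover <- list()
  for (t in seq_len(nrow(index$terms))) {
    seqw <- index$terms$words[[t]]
    m <- index$terms$method_id[t]
    L <- length(seqw)
    if (L <= n) {
      for (s in 1:(n - L + 1)) {
        if (identical(words[s:(s + L - 1)], seqw)) {
          events[[length(events) + 1]] <-
            data.frame(method_id = m, kind = "full", position = s - 1)
          full_cover[[m]] <- union(full_cover[[m]], s:(s + L - 1))
        }
      }
    }
  }
  for (t in seq_len(nrow(index$terms))) {
    cw <- index$terms$content_words[[t]]
    if (length(cw) < subset_min) next
    seen <- character()
    for (s in 1:max(1, n - window + 1)) {
      win <- s:min(n, s + window - 1)
      hit <- win[words[win] %in% cw]
      if (length(unique(words[hit])) >= subset_min) {
        key <- paste(hit, collapse = ",")
        if (!(key %in% seen)) {
          seen <- c(seen, key)
          events[[length(events) + 1]] <- data.frame(
            method_id = index$terms$method_id[t], kind = "subset",
            position = hit[1] - 1
          )
        }
      }
    }
  }
  for (s in seq_len(n)) {
    for (m in unique(index$words$method_id[index$words$word == words[s]])) {
      if (!is.null(full_cover[[m]]) && s %in% full_cover[[m]]) next
      events[[length(events) + 1]] <-
        data.frame(method_id = m, kind = "submatch", position = s - 1)
    }
  }
  if (length(events) == 0) {
    return(data.frame(method_id = character(), kind = character(),
                      position = integer()))
  }
  ev <- do.call(rbind, events)
  ev[order(ev$position, ev$method_id, ev$kind), , drop = FALSE]
}
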
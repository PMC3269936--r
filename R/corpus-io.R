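# Readers/writers for the external formats (document collections, PSI-MI
# ontology in OBO, gold annotations, prediction files) and method-section
# zoning.

#' Read a document collection
#'
#' One record per line, JSON object with keys `id`, `title`, `body` and an
#' optional `mesh` array of raw MeSH strings. Input order is preserved and
#' text is not modified in any way.
#'
#' @param path path to a UTF-8 JSON-lines file.
#' @return a tibble with columns `doc_id`, `title`, `body`, `mesh`
#'   (list-column of character vectors), `method_start`, `method_end`,
#'   `zoning_fallback` (the last three `NA` until
#'   [detect_method_section()] is run).
#' @seealso [write_documents()], [detect_method_section()]
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("read_documents(): no such file: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_documents())
  recs <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) {
        rlang::abort(paste0("read_documents(): malformed record at line ", i,
                            ": ", conditionMessage(e)))
      }
    )
    for (field in c("id", "title", "body")) {
      if (is.null(rec[[field]]) || !nzchar(as.character(rec[[field]])[1])) {
        if (field != "id" && !is.null(rec[[field]])) next
        rlang::abort(paste0("read_documents(): record at line ", i,
                            " missing field '", field, "'"))
      }
    }
    tibble::tibble(
      doc_id = as.character(rec$id),
      title = as.character(rec$title),
      body = as.character(rec$body),
      mesh = list(as.character(rec$mesh %||% character()))
    )
  })
  docs <- dplyr::bind_rows(recs)
  dup <- docs$doc_id[duplicated(docs$doc_id)]
  if (length(dup) > 0L) {
    rlang::abort(paste0("read_documents(): duplicate doc_id: ",
                        paste(unique(dup), collapse = ", ")))
  }
  docs$method_start <- NA_integer_
  docs$method_end <- NA_integer_
  docs$zoning_fallback <- NA
  docs
}

empty_documents <- function() {
  tibble::tibble(
    doc_id = character(), title = character(), body = character(),
    mesh = list(), method_start = integer(), method_end = integer(),
    zoning_fallback = logical()
  )
}

#' Write a document collection
#'
#' @param docs a documents tibble as returned by [read_documents()] or the
#'   fixture generators.
#' @param path output path; JSON-lines, one record per line.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  lines <- purrr::pmap_chr(
    list(docs$doc_id, docs$title, docs$body, docs$mesh),
    function(id, title, body, mesh) {
      jsonlite::toJSON(
        list(id = id, title = title, body = body, mesh = mesh),
        auto_unbox = TRUE
      )
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a PSI-MI-style method ontology from an OBO file
#'
#' Every `[Term]` stanza whose id matches `MI:dddd` becomes one entry;
#' quoted synonym strings are extracted from `synonym:` lines; stanzas
#' flagged `is_obsolete: true` are skipped, and stanzas without a `name:`
#' line are skipped with a warning.
#'
#' @param path path to an OBO 1.2 file.
#' @return a tibble with columns `method_id`, `name`, `synonyms`
#'   (list-column of character vectors).
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("read_ontology(): no such file: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # split into stanzas at [Term] / other stanza headers
  header_idx <- grep("^\\[.*\\]\\s*$", lines)
  if (length(header_idx) == 0L) return(empty_ontology())
  bounds <- c(header_idx, length(lines) + 1L)
  entries <- list()
  for (k in seq_along(header_idx)) {
    if (trimws(lines[header_idx[k]]) != "[Term]") next
    chunk <- lines[seq(header_idx[k] + 1L, bounds[k + 1L] - 1L)]
    getval <- function(key) {
      hit <- grep(paste0("^", key, ":"), chunk, value = TRUE)
      trimws(sub(paste0("^", key, ":"), "", hit))
    }
    id <- getval("id")
    if (length(id) == 0L || !grepl("^MI:\\d{4}$", id[1])) next
    if (any(grepl("^is_obsolete:\\s*true", chunk))) next
    nm <- getval("name")
    if (length(nm) == 0L || !nzchar(nm[1])) {
      rlang::warn(paste0("read_ontology(): skipping stanza ", id[1],
                         " without a name"))
      next
    }
    syn_lines <- getval("synonym")
    syns <- stringr::str_match(syn_lines, "\"([^\"]*)\"")[, 2]
    syns <- syns[!is.na(syns) & nzchar(syns)]
    entries[[length(entries) + 1L]] <- tibble::tibble(
      method_id = id[1], name = nm[1], synonyms = list(syns)
    )
  }
  if (length(entries) == 0L) return(empty_ontology())
  ont <- dplyr::bind_rows(entries)
  if (anyDuplicated(ont$method_id)) {
    rlang::abort("read_ontology(): duplicate method ids in file")
  }
  ont
}

empty_ontology <- function() {
  tibble::tibble(method_id = character(), name = character(), synonyms = list())
}

#' Write a method ontology as OBO
#'
#' @param ontology tibble with `method_id`, `name`, `synonyms`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(ontology))) {
    out <- c(out, "[Term]",
             paste0("id: ", ontology$method_id[i]),
             paste0("name: ", ontology$name[i]))
    for (s in ontology$synonyms[[i]]) {
      out <- c(out, paste0("synonym: \"", s, "\" EXACT []"))
    }
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Parse one raw MeSH string
#'
#' The textual MeSH dialect is a signed descriptor optionally followed by a
#' parenthesised, `;`-separated list of signed qualifiers, e.g.
#' `"-Signal Transduction (-drug effects; +physiology)"`. Descriptor and
#' qualifier words are lowercased and split on whitespace; each qualifier
#' keeps its `+`/`-` sign.
#'
#' @param line a single raw MeSH string.
#' @return a list with elements `descriptor` (character vector of lowercased
#'   words) and `qualifiers` (list of `list(sign=, words=)`).
#' @examples
#' parse_mesh_line("-Signal Transduction (-drug effects; +physiology)")
#' @export
parse_mesh_line <- function(line) {
  stopifnot(is.character(line), length(line) == 1L)
  m <- stringr::str_match(
    trimws(line),
    "^([+-]?)\\s*([^()]+?)\\s*(?:\\(([^()]*)\\))?$"
  )
  fail <- function() {
    rlang::abort(paste0("parse_mesh_line(): cannot parse MeSH string: '",
                        line, "'"))
  }
  if (is.na(m[1, 1])) fail()
  desc <- tolower(strsplit(trimws(m[1, 3]), "\\s+")[[1]])
  desc <- desc[nzchar(desc)]
  if (length(desc) == 0L) fail()
  qualifiers <- list()
  if (!is.na(m[1, 4]) && nzchar(trimws(m[1, 4]))) {
    parts <- trimws(strsplit(m[1, 4], ";", fixed = TRUE)[[1]])
    for (part in parts) {
      qm <- stringr::str_match(part, "^([+-])\\s*(.+)$")
      if (is.na(qm[1, 1])) fail()
      qwords <- tolower(strsplit(trimws(qm[1, 3]), "\\s+")[[1]])
      qwords <- qwords[nzchar(qwords)]
      if (length(qwords) == 0L) fail()
      qualifiers[[length(qualifiers) + 1L]] <-
        list(sign = qm[1, 2], words = qwords)
    }
  }
  list(descriptor = desc, qualifiers = qualifiers)
}

#' Locate the methods section of each document
#'
#' Scans the body line by line. The section starts at the first line
#' matching a methods heading and ends just before the next closing heading
#' (results/discussion/acknowledgements/references) or at the end of the
#' body. When no methods heading matches, the span is the whole body and
#' `zoning_fallback` is set. Offsets are 0-based half-open character
#' positions into `body`.
#'
#' @param docs a documents tibble.
#' @param heading_patterns regular expressions (case-insensitive, matched at
#'   line start) that open a methods section.
#' @param closing_patterns regular expressions that terminate it.
#' @return `docs` with `method_start`, `method_end`, `zoning_fallback`
#'   filled in.
#' @export
detect_method_section <- function(
    docs,
    heading_patterns = c("^\\s*materials?\\s+and\\s+methods\\b",
                         "^\\s*methods\\b",
                         "^\\s*experimental\\s+procedures\\b"),
    closing_patterns = c("^\\s*results\\b", "^\\s*discussion\\b",
                         "^\\s*acknowledg", "^\\s*references\\b")) {
  spans <- purrr::map(docs$body, function(body) {
    n <- nchar(body)
    if (n == 0L) return(list(start = 0L, end = 0L, fallback = TRUE))
    lines <- strsplit(body, "\n", fixed = TRUE)[[1]]
    if (length(lines) == 0L) lines <- ""
    # 0-based start offset of each line
    starts <- c(0L, cumsum(nchar(lines) + 1L))[seq_along(lines)]
    hit <- function(pats, from) {
      for (i in seq(from, length(lines))) {
        if (any(vapply(pats, function(p) {
          grepl(p, lines[i], ignore.case = TRUE, perl = TRUE)
        }, logical(1)))) return(i)
      }
      0L
    }
    h <- hit(heading_patterns, 1L)
    if (h == 0L) return(list(start = 0L, end = n, fallback = TRUE))
    e <- if (h < length(lines)) hit(closing_patterns, h + 1L) else 0L
    end <- if (e == 0L) n else starts[e]
    # trim the trailing newline before the closing heading
    if (e != 0L && end > 0L) end <- end - 1L
    list(start = starts[h], end = as.integer(end), fallback = FALSE)
  })
  docs$method_start <- purrr::map_int(spans, "start")
  docs$method_end <- purrr::map_int(spans, "end")
  docs$zoning_fallback <- purrr::map_lgl(spans, "fallback")
  docs
}

# text of one document restricted to a zone; zone "methods" needs
# detect_method_section() to have run (falls back to the whole body)
zone_text <- function(docs, zone = c("methods", "all")) {
  zone <- match.arg(zone)
  if (zone == "all") return(paste(docs$title, docs$body))
  purrr::pmap_chr(
    list(docs$body, docs$method_start, docs$method_end),
    function(body, s, e) {
      if (is.na(s) || is.na(e)) body else substr(body, s + 1L, e)
    }
  )
}

#' Read gold annotations
#'
#' @param path TSV file. Method-detection gold has rows `doc_id<TAB>method_id`;
#'   article-classification gold has rows `doc_id<TAB>label` with label 0 or 1.
#' @return for `read_gold_imt()` a tibble `doc_id`, `method_id`; for
#'   `read_gold_act()` a tibble `doc_id`, `label` (integer 0/1).
#' @export
read_gold_imt <- function(path) {
  rows <- read_tsv_rows(path, 2L, "read_gold_imt")
  tibble::tibble(doc_id = rows[[1]], method_id = rows[[2]])
}

#' @rdname read_gold_imt
#' @export
read_gold_act <- function(path) {
  rows <- read_tsv_rows(path, 2L, "read_gold_act")
  lab <- suppressWarnings(as.integer(rows[[2]]))
  bad <- which(is.na(lab) | !(lab %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    rlang::abort(paste0("read_gold_act(): label not 0/1 at line ", bad[1]))
  }
  tibble::tibble(doc_id = rows[[1]], label = lab)
}

read_tsv_rows <- function(path, ncol, who) {
  if (!file.exists(path)) {
    rlang::abort(paste0(who, "(): no such file: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncol)
  if (length(bad) > 0L) {
    rlang::abort(paste0(who, "(): expected ", ncol, " tab-separated columns",
                        " at line ", bad[1]))
  }
  lapply(seq_len(ncol), function(j) {
    vapply(parts, `[[`, character(1), j)
  })
}

#' Write and read prediction files
#'
#' Method-detection predictions are TSV rows
#' `doc_id<TAB>method_id<TAB>rank<TAB>confidence`; article-classification
#' predictions are `doc_id<TAB>class<TAB>confidence`. Confidences are
#' printed with 6 decimals, so write/read round-trips preserve them at that
#' precision.
#'
#' @param predictions a predictions tibble (see [rank_predictions()] and
#'   [act_predict()]).
#' @param path file path.
#' @param task `"imt"` (method detection) or `"act"` (article
#'   classification).
#' @return `write_predictions()` returns `path` invisibly;
#'   `read_predictions()` returns the tibble.
#' @export
write_predictions <- function(predictions, path, task = c("imt", "act")) {
  task <- match.arg(task)
  if (task == "imt") {
    lines <- sprintf("%s\t%s\t%d\t%.6f",
                     predictions$doc_id, predictions$method_id,
                     as.integer(predictions$rank), predictions$confidence)
  } else {
    lines <- sprintf("%s\t%d\t%.6f",
                     predictions$doc_id, as.integer(predictions$class),
                     predictions$confidence)
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path, task = c("imt", "act")) {
  task <- match.arg(task)
  if (task == "imt") {
    rows <- read_tsv_rows(path, 4L, "read_predictions")
    tibble::tibble(doc_id = rows[[1]], method_id = rows[[2]],
                   rank = as.integer(rows[[3]]),
                   confidence = as.numeric(rows[[4]]))
  } else {
    rows <- read_tsv_rows(path, 3L, "read_predictions")
    tibble::tibble(doc_id = rows[[1]], class = as.integer(rows[[2]]),
                   confidence = as.numeric(rows[[3]]))
  }
}
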
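# Shared text processing: tokenization, stemming (see porter.R), bigrams.

#' Tokenize text into word tokens with character offsets
#'
#' Tokens are maximal runs of letters and digits; hyphens and slashes are
#' word-internal, so `"two-hybrid"` and `"ERK1/2"` stay single tokens.
#' Punctuation is dropped. Offsets are 0-based half-open into the source
#' string, so `substr(text, start + 1, end)` recovers the surface form.
#'
#' @param text a single string (may be empty).
#' @param stem_tokens add a `stem` column (lowercased Porter stem of the
#'   surface form)? Default `TRUE`.
#' @return a tibble with columns `index` (0-based position in the token
#'   sequence), `surface`, `stem` (if requested), `start`, `end`.
#' @examples
#' cm_tokenize("X-ray; crystallography.")
#' @export
cm_tokenize <- function(text, stem_tokens = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble::tibble(
    index = integer(), surface = character(),
    start = integer(), end = integer()
  )
  if (is.na(text) || !nzchar(text)) {
    if (stem_tokens) empty$stem <- character()
    return(empty[, intersect(c("index", "surface", "stem", "start", "end"),
                             names(empty))])
  }
  m <- stringr::str_locate_all(
    text, "[\\p{L}\\p{N}]+(?:[-/][\\p{L}\\p{N}]+)*"
  )[[1]]
  if (nrow(m) == 0L) {
    if (stem_tokens) empty$stem <- character()
    return(empty)
  }
  surface <- stringr::str_sub(text, m[, 1], m[, 2])
  out <- tibble::tibble(
    index = seq_len(nrow(m)) - 1L,
    surface = surface,
    start = as.integer(m[, 1] - 1L),
    end = as.integer(m[, 2])
  )
  if (stem_tokens) {
    out$stem <- cm_stem(out$surface)
    out <- out[, c("index", "surface", "stem", "start", "end")]
  }
  out
}

#' Adjacent bigrams of a token sequence
#'
#' @param stems character vector of stems (or any words) in document order.
#' @return a tibble with columns `w1`, `w2`; `n` input words yield
#'   `max(0, n - 1)` rows, in order.
#' @examples
#' cm_bigrams(c("interact", "with", "the"))
#' @export
cm_bigrams <- function(stems) {
  stopifnot(is.character(stems))
  n <- length(stems)
  if (n < 2L) return(tibble::tibble(w1 = character(), w2 = character()))
  tibble::tibble(w1 = stems[-n], w2 = stems[-1L])
}

# lowercased surface words of one document zone; internal helper shared by
# the IMT estimators and scorers (IMT matching uses surfaces, not stems)
doc_words <- function(text) {
  tolower(cm_tokenize(text, stem_tokens = FALSE)$surface)
}
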
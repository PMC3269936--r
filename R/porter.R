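# Porter (1980) English stemmer. Implemented here because the suffix-stripping
# rules are load-bearing for feature identity across the package; follows the
# canonical step structure (1a-1c, 2-4, 5a-5b) of the reference implementation.

porter_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!porter_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m: number of VC sequences in chars[1..j]
porter_m <- function(chars, j) {
  if (j < 1L) return(0L)
  types <- vapply(seq_len(j), function(i) porter_is_cons(chars, i), logical(1))
  rle_t <- rle(types)
  v <- rle_t$values
  # count transitions vowel-run -> consonant-run
  if (length(v) < 2L) return(0L)
  sum(v[-length(v)] == FALSE & v[-1L] == TRUE)
}

porter_has_vowel <- function(chars, j) {
  if (j < 1L) return(FALSE)
  any(!vapply(seq_len(j), function(i) porter_is_cons(chars, i), logical(1)))
}

porter_double_cons <- function(chars, j) {
  j >= 2L && chars[j] == chars[j - 1L] && porter_is_cons(chars, j)
}

# consonant-vowel-consonant ending, last consonant not w, x or y
porter_cvc <- function(chars, j) {
  if (j < 3L) return(FALSE)
  porter_is_cons(chars, j) && !porter_is_cons(chars, j - 1L) &&
    porter_is_cons(chars, j - 2L) && !(chars[j] %in% c("w", "x", "y"))
}

porter_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)
  b <- strsplit(word, "", fixed = TRUE)[[1]]

  ends_with <- function(suf) {
    ls <- nchar(suf)
    lb <- length(b)
    lb > ls && paste(b[(lb - ls + 1L):lb], collapse = "") == suf
  }
  stem_len <- function(suf) length(b) - nchar(suf)

  # Step 1a
  if (ends_with("sses")) {
    b <- b[seq_len(length(b) - 2L)]
  } else if (ends_with("ies")) {
    b <- c(b[seq_len(length(b) - 3L)], "i")
  } else if (!ends_with("ss") && length(b) > 1L && b[length(b)] == "s") {
    b <- b[seq_len(length(b) - 1L)]
  }

  # Step 1b
  step1b_extra <- FALSE
  if (ends_with("eed")) {
    if (porter_m(b, stem_len("eed")) > 0L) b <- b[seq_len(length(b) - 1L)]
  } else if (ends_with("ed") && porter_has_vowel(b, stem_len("ed"))) {
    b <- b[seq_len(stem_len("ed"))]
    step1b_extra <- TRUE
  } else if (ends_with("ing") && porter_has_vowel(b, stem_len("ing"))) {
    b <- b[seq_len(stem_len("ing"))]
    step1b_extra <- TRUE
  }
  if (step1b_extra) {
    j <- length(b)
    tail2 <- if (j >= 2L) paste(b[(j - 1L):j], collapse = "") else ""
    if (tail2 %in% c("at", "bl", "iz")) {
      b <- c(b, "e")
    } else if (porter_double_cons(b, j) && !(b[j] %in% c("l", "s", "z"))) {
      b <- b[seq_len(j - 1L)]
    } else if (porter_m(b, j) == 1L && porter_cvc(b, j)) {
      b <- c(b, "e")
    }
  }

  # Step 1c
  if (length(b) > 1L && b[length(b)] == "y" &&
      porter_has_vowel(b, length(b) - 1L)) {
    b[length(b)] <- "i"
  }

  apply_rules <- function(b, rules, cond) {
    for (k in seq_along(rules)) {
      suf <- names(rules)[k]
      ls <- nchar(suf)
      lb <- length(b)
      if (lb > ls && paste(b[(lb - ls + 1L):lb], collapse = "") == suf) {
        j <- lb - ls
        if (cond(b, j, suf)) {
          rep_chars <- strsplit(rules[[k]], "", fixed = TRUE)[[1]]
          b <- c(b[seq_len(j)], rep_chars)
        }
        return(b)  # longest-match semantics: first matching suffix decides
      }
    }
    b
  }

  # Step 2 (m > 0); rule order encodes longest-match by penultimate letter
  step2 <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", bli = "ble", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble", logi = "log"
  )
  b <- apply_rules(b, as.list(step2), function(b, j, suf) porter_m(b, j) > 0L)

  # Step 3 (m > 0)
  step3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
             ical = "ic", ful = "", ness = "")
  b <- apply_rules(b, as.list(step3), function(b, j, suf) porter_m(b, j) > 0L)

  # Step 4 (m > 1); "ion" requires preceding s or t
  step4 <- c(al = "", ance = "", ence = "", er = "", ic = "", able = "",
             ible = "", ant = "", ement = "", ment = "", ent = "", ion = "",
             ou = "", ism = "", ate = "", iti = "", ous = "", ive = "",
             ize = "")
  b <- apply_rules(b, as.list(step4), function(b, j, suf) {
    ok <- porter_m(b, j) > 1L
    if (suf == "ion") ok <- ok && j >= 1L && b[j] %in% c("s", "t")
    ok
  })

  # Step 5a
  j <- length(b)
  if (j > 1L && b[j] == "e") {
    m <- porter_m(b, j - 1L)
    if (m > 1L || (m == 1L && !porter_cvc(b, j - 1L))) {
      b <- b[seq_len(j - 1L)]
    }
  }

  # Step 5b
  j <- length(b)
  if (porter_m(b, j) > 1L && porter_double_cons(b, j) && b[j] == "l") {
    b <- b[seq_len(j - 1L)]
  }

  paste(b, collapse = "")
}

#' Stem a word with the Porter English stemmer
#'
#' Deterministic suffix-stripping stemmer used for all bag-of-stems and
#' bigram features. Input is lowercased before stemming. Tokens containing
#' characters outside `a-z` (digits, hyphens, slashes) are passed through the
#' same rules; in practice the rules only fire on alphabetic tails, so mixed
#' tokens such as `"erk1/2"` are left intact.
#'
#' @param words character vector of non-empty words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' cm_stem(c("interacts", "interacting", "protein"))
#' @export
cm_stem <- function(words) {
  stopifnot(is.character(words))
  if (any(!nzchar(words))) {
    rlang::abort("cm_stem(): empty words are not allowed")
  }
  vapply(tolower(words), porter_stem_one, character(1), USE.NAMES = FALSE)
}
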
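#' Porter stem of a token
#'
#' Reduces an English word to its stem with the Porter (1980) suffix-stripping
#' algorithm, the normalization used throughout the pipeline so that inflected
#' trigger words ("binds", "binding", "bind") collapse onto one lexicon key.
#'
#' @param token Character vector of words. Each word is lowercased before
#'   stemming; words of two letters or fewer are returned unchanged.
#' @return Character vector of stems, same length as `token`.
#' @examples
#' porter_stem(c("binding", "created", "antagonists"))
#' @export
porter_stem <- function(token) {
  vapply(tolower(token), porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(w) {
  if (nchar(w) <= 2 || grepl("[^a-z]", w)) {
    return(w)
  }
  w <- pt_step1a(w)
  w <- pt_step1b(w)
  w <- pt_step1c(w)
  w <- pt_step2(w)
  w <- pt_step3(w)
  w <- pt_step4(w)
  w <- pt_step5a(w)
  pt_step5b(w)
}

# consonant/vowel classification: y is a vowel when preceded by a consonant
pt_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) {
    return(FALSE)
  }
  if (ch == "y") {
    if (i == 1L) {
      return(TRUE)
    }
    return(!pt_is_cons(chars, i - 1L))
  }
  TRUE
}

pt_cv <- function(w) {
  chars <- strsplit(w, "")[[1]]
  vapply(seq_along(chars), function(i) pt_is_cons(chars, i), logical(1))
}

# measure m in the [C](VC)^m[V] decomposition: after an optional leading
# consonant run the classification alternates V,C,V,C,... and m is the number
# of consonant runs left
pt_measure <- function(w) {
  if (!nzchar(w)) {
    return(0L)
  }
  runs <- rle(pt_cv(w))$values
  if (length(runs) && runs[1]) {
    runs <- runs[-1]
  }
  sum(runs)
}

pt_has_vowel <- function(w) {
  nzchar(w) && any(!pt_cv(w))
}

pt_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2) {
    return(FALSE)
  }
  a <- substr(w, n - 1, n - 1)
  b <- substr(w, n, n)
  a == b && pt_is_cons(strsplit(w, "")[[1]], n)
}

# *o: stem ends cvc where the final consonant is not w, x or y
pt_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3) {
    return(FALSE)
  }
  cons <- pt_cv(w)
  last <- substr(w, n, n)
  cons[n - 2] && !cons[n - 1] && cons[n] && !last %in% c("w", "x", "y")
}

pt_ends <- function(w, suf) {
  n <- nchar(w)
  k <- nchar(suf)
  n > k && substr(w, n - k + 1, n) == suf
}

pt_chop <- function(w, suf) substr(w, 1, nchar(w) - nchar(suf))

pt_step1a <- function(w) {
  if (pt_ends(w, "sses")) {
    return(pt_chop(w, "es"))
  }
  if (pt_ends(w, "ies")) {
    return(pt_chop(w, "es"))
  }
  if (pt_ends(w, "ss")) {
    return(w)
  }
  if (pt_ends(w, "s")) {
    return(pt_chop(w, "s"))
  }
  w
}

pt_step1b <- function(w) {
  if (pt_ends(w, "eed")) {
    stem <- pt_chop(w, "eed")
    if (pt_measure(stem) > 0) {
      return(paste0(stem, "ee"))
    }
    return(w)
  }
  stripped <- NULL
  if (pt_ends(w, "ed") && pt_has_vowel(pt_chop(w, "ed"))) {
    stripped <- pt_chop(w, "ed")
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_chop(w, "ing"))) {
    stripped <- pt_chop(w, "ing")
  }
  if (is.null(stripped)) {
    return(w)
  }
  w <- stripped
  if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
    return(paste0(w, "e"))
  }
  if (pt_double_cons(w) && !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
    return(substr(w, 1, nchar(w) - 1))
  }
  if (pt_measure(w) == 1 && pt_cvc(w)) {
    return(paste0(w, "e"))
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends(w, "y") && pt_has_vowel(pt_chop(w, "y"))) {
    return(paste0(pt_chop(w, "y"), "i"))
  }
  w
}

# rule tables for steps 2-4: longest matching suffix wins; if its condition
# fails no other suffix in the step is tried (first-match semantics)
pt_apply_rules <- function(w, rules, min_m) {
  sufs <- names(rules)
  sufs <- sufs[order(-nchar(sufs))]
  for (suf in sufs) {
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, suf)
      if (pt_measure(stem) > min_m) {
        return(paste0(stem, rules[[suf]]))
      }
      return(w)
    }
  }
  w
}

pt_step2 <- function(w) {
  rules <- c(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  )
  pt_apply_rules(w, rules, 0L)
}

pt_step3 <- function(w) {
  rules <- c(
    icate = "ic", ative = "", alize = "al", iciti = "ic",
    ical = "ic", ful = "", ness = ""
  )
  pt_apply_rules(w, rules, 0L)
}

pt_step4 <- function(w) {
  sufs <- c(
    "ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
    "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er", "ic", "ou"
  )
  sufs <- sufs[order(-nchar(sufs))]
  for (suf in sufs) {
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, suf)
      ok <- pt_measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) {
        return(stem)
      }
      return(w)
    }
  }
  w
}

pt_step5a <- function(w) {
  if (pt_ends(w, "e")) {
    stem <- pt_chop(w, "e")
    m <- pt_measure(stem)
    if (m > 1 || (m == 1 && !pt_cvc(stem))) {
      return(stem)
    }
  }
  w
}

pt_step5b <- function(w) {
  if (pt_measure(w) > 1 && pt_double_cons(w) &&
    substr(w, nchar(w), nchar(w)) == "l") {
    return(substr(w, 1, nchar(w) - 1))
  }
  w
}
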
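# Porter stemming algorithm (1980), used by the stem-matching stage of
# meteor_lite. Operates on single lowercase ASCII words.

porter_is_cons <- function(w, i) {
  ch <- substr(w, i, i)
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") return(if (i == 1L) TRUE else !porter_is_cons(w, i - 1L))
  TRUE
}

# measure m: number of VC sequences in the stem
porter_m <- function(w) {
  if (!nzchar(w)) return(0L)
  types <- vapply(seq_len(nchar(w)), function(i) porter_is_cons(w, i),
                  logical(1))
  r <- rle(types)$values
  if (length(r) && r[1]) r <- r[-1]              # leading C run
  if (length(r) && !r[length(r)]) r <- r[-length(r)]  # trailing V run
  sum(r) # remaining TRUE entries, one per VC pair
}

porter_has_vowel <- function(w) {
  any(!vapply(seq_len(nchar(w)), function(i) porter_is_cons(w, i),
              logical(1)))
}

porter_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) &&
    porter_is_cons(w, n)
}

# *o: stem ends cvc where the final c is not w, x or y
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  porter_is_cons(w, n - 2L) && !porter_is_cons(w, n - 1L) &&
    porter_is_cons(w, n) && !(substr(w, n, n) %in% c("w", "x", "y"))
}

ends_with <- function(w, s) {
  n <- nchar(w); k <- nchar(s)
  n >= k && substr(w, n - k + 1L, n) == s
}

chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# replace suffix `s` by `r` if the remaining stem has measure > m_min
porter_rule <- function(w, s, r, m_min) {
  stem <- chop(w, nchar(s))
  if (porter_m(stem) > m_min) paste0(stem, r) else w
}

#' Porter stem of a word
#'
#' Classic suffix-stripping stemmer; maps morphological variants
#' ("measuring", "measured", "measures") onto a shared stem.
#'
#' @param word single lowercase word.
#' @return Stemmed word.
#' @export
porter_stem <- function(word) {
  w <- word
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (ends_with(w, "sses")) w <- chop(w, 2L)
  else if (ends_with(w, "ies")) w <- chop(w, 2L)
  else if (!ends_with(w, "ss") && ends_with(w, "s")) w <- chop(w, 1L)

  # step 1b
  if (ends_with(w, "eed")) {
    if (porter_m(chop(w, 3L)) > 0L) w <- chop(w, 1L)
  } else {
    hit <- FALSE
    if (ends_with(w, "ed") && porter_has_vowel(chop(w, 2L))) {
      w <- chop(w, 2L); hit <- TRUE
    } else if (ends_with(w, "ing") && porter_has_vowel(chop(w, 3L))) {
      w <- chop(w, 3L); hit <- TRUE
    }
    if (hit) {
      if (ends_with(w, "at") || ends_with(w, "bl") || ends_with(w, "iz"))
        w <- paste0(w, "e")
      else if (porter_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))
        w <- chop(w, 1L)
      else if (porter_m(w) == 1L && porter_cvc(w)) w <- paste0(w, "e")
    }
  }

  # step 1c
  if (ends_with(w, "y") && porter_has_vowel(chop(w, 1L)))
    w <- paste0(chop(w, 1L), "i")

  # step 2
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent",
          eli = "e", ousli = "ous", ization = "ize", ation = "ate",
          ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
          ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  for (s in names(s2)) {
    if (ends_with(w, s)) { w <- porter_rule(w, s, s2[[s]], 0L); break }
  }

  # step 3
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
          ical = "ic", ful = "", ness = "")
  for (s in names(s3)) {
    if (ends_with(w, s)) { w <- porter_rule(w, s, s3[[s]], 0L); break }
  }

  # step 4
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
          "ement", "ment", "ent", "ou", "ism", "ate", "iti", "ous",
          "ive", "ize")
  for (s in s4) {
    if (ends_with(w, s)) {
      stem <- chop(w, nchar(s))
      if (porter_m(stem) > 1L) w <- stem
      break
    }
  }
  if (ends_with(w, "ion")) {
    stem <- chop(w, 3L)
    if (porter_m(stem) > 1L && nzchar(stem) &&
        substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))
      w <- stem
  }

  # step 5a
  if (ends_with(w, "e")) {
    stem <- chop(w, 1L)
    m <- porter_m(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }
  # step 5b
  if (porter_m(w) > 1L && porter_double_cons(w) && ends_with(w, "l"))
    w <- chop(w, 1L)
  w
}
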
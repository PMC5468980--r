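# Porter stemming algorithm (original 1980 definition).  No suffix-stripping
# package ships with the supported environment, so the algorithm is
# implemented here and pinned by fixtures frozen from a reference
# implementation run in original-algorithm mode.

.pt_is_cons <- function(w, i) {
  ch <- substr(w, i, i)
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(w, i - 1L))
  }
  TRUE
}

# measure m of [C](VC)^m[V]
.pt_measure <- function(w) {
  n <- nchar(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .pt_is_cons(w, i), logical(1))
  rle_t <- rle(types)$values  # TRUE = consonant run
  # count VC pairs in the run sequence
  m <- 0L
  for (i in seq_along(rle_t)) {
    if (i > 1L && rle_t[i] && !rle_t[i - 1L]) m <- m + 1L
  }
  m
}

.pt_has_vowel <- function(w) {
  n <- nchar(w)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) .pt_is_cons(w, i), logical(1)))
}

.pt_ends_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) && .pt_is_cons(w, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.pt_ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  if (!(.pt_is_cons(w, n) && !.pt_is_cons(w, n - 1L) && .pt_is_cons(w, n - 2L)))
    return(FALSE)
  !(substr(w, n, n) %in% c("w", "x", "y"))
}

.pt_ends <- function(w, suf) {
  ns <- nchar(suf)
  nchar(w) >= ns && substring(w, nchar(w) - ns + 1L) == suf
}

.pt_chop <- function(w, suf) substr(w, 1L, nchar(w) - nchar(suf))

# rules: list of c(suffix, replacement); condition applied to stem after
# removing suffix; first matching suffix decides (lists ordered longest-first
# where suffixes overlap)
.pt_rule_list <- function(w, rules, cond) {
  for (r in rules) {
    if (.pt_ends(w, r[1])) {
      stem <- .pt_chop(w, r[1])
      if (cond(stem)) return(paste0(stem, r[2]))
      return(w)
    }
  }
  w
}

.pt_step1a <- function(w) {
  if (.pt_ends(w, "sses")) return(.pt_chop(w, "es"))
  if (.pt_ends(w, "ies"))  return(paste0(.pt_chop(w, "ies"), "i"))
  if (.pt_ends(w, "ss"))   return(w)
  if (.pt_ends(w, "s"))    return(.pt_chop(w, "s"))
  w
}

.pt_step1b <- function(w) {
  if (.pt_ends(w, "eed")) {
    stem <- .pt_chop(w, "eed")
    if (.pt_measure(stem) > 0L) return(.pt_chop(w, "d"))
    return(w)
  }
  stripped <- NULL
  if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, "ed"))) {
    stripped <- .pt_chop(w, "ed")
  } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, "ing"))) {
    stripped <- .pt_chop(w, "ing")
  }
  if (is.null(stripped)) return(w)
  w <- stripped
  if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
    return(paste0(w, "e"))
  }
  if (.pt_ends_double_cons(w) &&
      !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
    return(substr(w, 1L, nchar(w) - 1L))
  }
  if (.pt_measure(w) == 1L && .pt_ends_cvc(w)) return(paste0(w, "e"))
  w
}

.pt_step1c <- function(w) {
  if (.pt_ends(w, "y") && .pt_has_vowel(.pt_chop(w, "y"))) {
    return(paste0(.pt_chop(w, "y"), "i"))
  }
  w
}

.pt_step2_rules <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
  c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
  c("iviti", "ive"), c("biliti", "ble"))

.pt_step3_rules <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", ""))

.pt_step4_rules <- list(
  c("al", ""), c("ance", ""), c("ence", ""), c("er", ""), c("ic", ""),
  c("able", ""), c("ible", ""), c("ant", ""), c("ement", ""), c("ment", ""),
  c("ent", ""), c("ion", ""), c("ou", ""), c("ism", ""), c("ate", ""),
  c("iti", ""), c("ous", ""), c("ive", ""), c("ize", ""))

.pt_step4 <- function(w) {
  for (r in .pt_step4_rules) {
    if (.pt_ends(w, r[1])) {
      stem <- .pt_chop(w, r[1])
      if (r[1] == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        if (.pt_measure(stem) > 1L && last %in% c("s", "t")) return(stem)
      } else if (.pt_measure(stem) > 1L) {
        return(stem)
      }
      return(w)
    }
  }
  w
}

.pt_step5a <- function(w) {
  if (.pt_ends(w, "e")) {
    stem <- .pt_chop(w, "e")
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_ends_cvc(stem))) return(stem)
  }
  w
}

.pt_step5b <- function(w) {
  if (.pt_measure(w) > 1L && .pt_ends_double_cons(w) &&
      .pt_ends(w, "l")) {
    return(substr(w, 1L, nchar(w) - 1L))
  }
  w
}

.porter_one <- function(w) {
  if (nchar(w) <= 2L) return(w)
  w <- .pt_step1a(w)
  w <- .pt_step1b(w)
  w <- .pt_step1c(w)
  w <- .pt_rule_list(w, .pt_step2_rules, function(s) .pt_measure(s) > 0L)
  w <- .pt_rule_list(w, .pt_step3_rules, function(s) .pt_measure(s) > 0L)
  w <- .pt_step4(w)
  w <- .pt_step5a(w)
  .pt_step5b(w)
}

#' Porter stemmer
#'
#' Suffix-stripping stemmer following the original algorithm definition.
#' Words of one or two characters are returned unchanged.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of stems.
#' @examples
#' porter_stem(c("medications", "falling", "generalizations"))
#' @export
porter_stem <- function(words) {
  vapply(words, .porter_one, character(1), USE.NAMES = FALSE)
}
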
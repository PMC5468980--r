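# Lightweight rule-based English lemmatizer.  No dictionary lemmatizer is
# available in the supported offline environment, so inflections are reduced
# with a small exception table (vendored, versioned) plus regular
# plural / past-tense / participle rules.  The default pipeline stems after
# lemmatizing, so residual irregularities wash out in the bag of words.

.lemma_env <- new.env(parent = emptyenv())

.lemma_exceptions <- function() {
  if (is.null(.lemma_env$tab)) {
    path <- system.file("extdata", "lemma-exceptions.tsv",
                        package = "incidenttriage")
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    .lemma_env$tab <- setNames(tab$lemma, tab$form)
  }
  .lemma_env$tab
}

.vowels <- c("a", "e", "i", "o", "u")

.undouble <- function(w) {
  n <- nchar(w)
  last <- substr(w, n, n)
  if (n >= 3L && last == substr(w, n - 1L, n - 1L) &&
      !(last %in% c("l", "s", "z")) && !(last %in% .vowels)) {
    return(substr(w, 1L, n - 1L))
  }
  w
}

.lemma_one <- function(w, exc) {
  hit <- exc[w]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(w)
  # plurals
  if (n >= 5L && endsWith(w, "ies")) return(paste0(substr(w, 1, n - 3L), "y"))
  if (n >= 5L && (endsWith(w, "sses") || endsWith(w, "ches") ||
                  endsWith(w, "shes") || endsWith(w, "xes") ||
                  endsWith(w, "zes"))) {
    return(substr(w, 1, n - 2L))
  }
  if (n >= 4L && endsWith(w, "s") && !endsWith(w, "ss") &&
      !endsWith(w, "us") && !endsWith(w, "is")) {
    return(substr(w, 1, n - 1L))
  }
  # past tense
  if (n >= 5L && endsWith(w, "ied")) return(paste0(substr(w, 1, n - 3L), "y"))
  if (n >= 5L && endsWith(w, "ed") && !endsWith(w, "eed")) {
    return(.undouble(substr(w, 1, n - 2L)))
  }
  # present participle
  if (n >= 6L && endsWith(w, "ing")) {
    base <- .undouble(substr(w, 1, n - 3L))
    if (nchar(base) >= 3L) return(base)
  }
  w
}

#' Rule-based lemmatizer
#'
#' Reduces regular English inflections (plural, past tense, present
#' participle) and a vendored table of irregular forms to their base form.
#' Intentionally lightweight; see the methods vignette for scope.
#'
#' @param words Character vector of lowercase words.
#' @return Character vector of lemmas.
#' @examples
#' lemmatize_words(c("given", "fell", "injuries", "slipped"))
#' @export
lemmatize_words <- function(words) {
  exc <- .lemma_exceptions()
  vapply(words, .lemma_one, character(1), exc = exc, USE.NAMES = FALSE)
}
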
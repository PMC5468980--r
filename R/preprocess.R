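#' Normalize raw narrative text
#'
#' Strips everything but alphanumeric characters, lower-cases, and collapses
#' whitespace.  Digits are retained (only non-alphanumerics are removed).
#' The operation is idempotent.
#'
#' @param text Character vector of raw narratives.
#' @return Character vector of the same length containing only lowercase
#'   alphanumerics separated by single spaces.
#' @examples
#' normalize_text("Pt FELL; BP 80/40!")
#' @export
normalize_text <- function(text) {
  if (length(text) == 0L) return(character(0))
  out <- tolower(text)
  out <- gsub("[^a-z0-9]+", " ", out)
  trimws(out)
}

#' Packaged English stop-word list
#'
#' The classic 127-word English list, vendored with the package so results
#' do not drift with external library versions.
#'
#' @return Character vector of stop words.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords-en.txt", package = "incidenttriage")
  readLines(path, warn = FALSE)
}

tokenize <- function(text) {
  toks <- strsplit(normalize_text(text), " ", fixed = TRUE)
  lapply(toks, function(x) x[nzchar(x)])
}

#' Preprocess one narrative into a token document
#'
#' Pipeline: normalize, whitespace-tokenize, drop stop words, drop tokens
#' shorter than 2 characters, lemmatize, then stem (Porter).  Order of the
#' last two stages is lemmatize-then-stem so the stemmer sees dictionary
#' forms of irregular inflections.
#'
#' @param report An incident report (list or one-row data frame with
#'   `report_id` and `narrative`), or a plain character narrative.
#' @param stopwords Character vector of stop words; defaults to the
#'   packaged list.
#' @param min_token_len Minimum token length retained (default 2; tokens
#'   with fewer than two characters are removed).
#' @param stem,lemmatize Logical switches for the two reduction stages.
#' @return A `token_doc`: list with `report_id` and `tokens`.
#' @examples
#' preprocess_report("Patient was given the wrong medication")$tokens
#' @export
preprocess_report <- function(report, stopwords = default_stopwords(),
                              min_token_len = 2L, stem = TRUE,
                              lemmatize = TRUE) {
  if (is.character(report)) {
    report <- list(report_id = NA_character_, narrative = report)
  }
  toks <- .refine_tokens(tokenize(report$narrative)[[1]], stopwords,
                         min_token_len, stem, lemmatize)
  structure(list(report_id = report$report_id, tokens = toks),
            class = "token_doc")
}

# reduction memoized over unique surface forms (corpora repeat a small
# vocabulary many thousands of times)
.reduce_map <- function(uniq, stem, lemmatize) {
  m <- uniq
  if (lemmatize && length(m)) m <- lemmatize_words(m)
  if (stem && length(m)) m <- porter_stem(m)
  setNames(m, uniq)
}

.refine_tokens <- function(toks, stopwords, min_token_len, stem, lemmatize,
                           map = NULL) {
  if (!length(toks)) return(character(0))
  toks <- toks[!(toks %in% stopwords)]
  toks <- toks[nchar(toks) >= min_token_len]
  if (!length(toks)) return(character(0))
  if (is.null(map)) map <- .reduce_map(unique(toks), stem, lemmatize)
  toks <- unname(map[toks])
  # reductions can in principle re-create stop words or short tokens
  toks[nchar(toks) >= min_token_len & !(toks %in% stopwords)]
}

#' Preprocess a whole corpus
#'
#' @param corpus A corpus data frame as returned by [generate_corpus()] or
#'   [read_corpus()] (columns `report_id`, `narrative`).
#' @inheritParams preprocess_report
#' @return List of `token_doc` objects, named by report id.
#' @export
preprocess_corpus <- function(corpus, stopwords = default_stopwords(),
                              min_token_len = 2L, stem = TRUE,
                              lemmatize = TRUE) {
  raw <- tokenize(corpus$narrative)
  map <- .reduce_map(unique(unlist(raw, use.names = FALSE)), stem, lemmatize)
  docs <- lapply(seq_len(nrow(corpus)), function(i) {
    structure(list(report_id = corpus$report_id[i],
                   tokens = .refine_tokens(raw[[i]], stopwords,
                                           min_token_len, stem, lemmatize,
                                           map = map)),
              class = "token_doc")
  })
  names(docs) <- corpus$report_id
  docs
}
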
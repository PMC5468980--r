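# Bag-of-words features: vocabulary with document frequencies, and binary /
# term-frequency / tf-idf weighting.  Matrices are kept sparse
# (Matrix::dgCMatrix) throughout; out-of-vocabulary tokens at prediction
# time are dropped.

#' Build a vocabulary from training documents
#'
#' Terms are the sorted union of training tokens; `doc_freq` counts the
#' number of documents containing a term (not occurrences).  The vocabulary
#' must be built from training-partition documents only — inverse document
#' frequencies and the feature space are never informed by held-out data.
#'
#' @param train_docs List of `token_doc` objects (see
#'   [preprocess_corpus()]), or a list of character vectors of tokens.
#' @return A `vocabulary`: list with `terms`, `index`, `doc_freq`,
#'   `n_train_docs`.
#' @export
build_vocabulary <- function(train_docs) {
  if (length(train_docs) == 0L) stop("train_docs must be non-empty")
  tok_sets <- lapply(train_docs, function(d) {
    unique(if (is.list(d)) d$tokens else d)
  })
  all_tokens <- unlist(tok_sets, use.names = FALSE)
  if (length(all_tokens) == 0L) {
    stop("all documents are empty: no features to build")
  }
  df <- table(all_tokens)
  terms <- sort(names(df))
  structure(list(terms = terms,
                 index = setNames(seq_along(terms), terms),
                 doc_freq = setNames(as.integer(df[terms]), terms),
                 n_train_docs = length(train_docs)),
            class = "vocabulary")
}

#' Inverse document frequency weights
#'
#' `idf(t) = ln(N / df(t))` (unsmoothed natural logarithm); a term present
#' in every training document gets weight 0.
#'
#' @param vocab A `vocabulary`.
#' @return Named numeric vector of idf weights in vocabulary order.
#' @export
compute_idf <- function(vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  setNames(log(vocab$n_train_docs / vocab$doc_freq), vocab$terms)
}

#' Vectorize token documents against a vocabulary
#'
#' @param docs List of `token_doc` objects or token character vectors.
#' @param vocab A `vocabulary` built from the training partition.
#' @param weighting `"binary"`, `"tf"`, or `"tfidf"`.
#' @return Sparse `dgCMatrix`, documents in rows, vocabulary terms in
#'   columns; a `weighting` attribute records the scheme.
#' @examples
#' v <- build_vocabulary(list(c("fall", "ward"), c("fall", "med"),
#'                            c("med", "dose")))
#' vectorize(list(c("fall", "fall", "ward")), v, "tf")
#' @export
vectorize <- function(docs, vocab, weighting = c("binary", "tf", "tfidf")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(vocab, "vocabulary"))
  n <- length(docs)
  p <- length(vocab$terms)
  trip <- lapply(seq_len(n), function(d) {
    toks <- docs[[d]]
    if (is.list(toks)) toks <- toks$tokens
    cols <- vocab$index[toks]
    cols <- cols[!is.na(cols)]           # OOV tokens dropped
    if (!length(cols)) return(NULL)
    cnt <- tabulate(cols, nbins = p)
    nz <- which(cnt > 0L)
    list(i = rep.int(d, length(nz)), j = nz, x = as.numeric(cnt[nz]))
  })
  trip <- trip[!vapply(trip, is.null, logical(1))]
  ii <- unlist(lapply(trip, `[[`, "i"), use.names = FALSE)
  jj <- unlist(lapply(trip, `[[`, "j"), use.names = FALSE)
  xx <- unlist(lapply(trip, `[[`, "x"), use.names = FALSE)
  if (is.null(ii)) { ii <- jj <- integer(0); xx <- numeric(0) }
  if (weighting == "binary") xx <- as.numeric(xx >= 1)
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, p),
                            dimnames = list(NULL, vocab$terms))
  if (weighting == "tfidf") {
    idf <- compute_idf(vocab)
    m <- m %*% Matrix::Diagonal(p, idf)
    colnames(m) <- vocab$terms
  }
  m <- as(m, "CsparseMatrix")
  attr(m, "weighting") <- weighting
  m
}

#' Persist / load a vocabulary as TSV
#'
#' Layout: a one-line header comment carrying `N` (number of training
#' documents), then tab-separated columns `term`, `index`, `df`.
#'
#' @param vocab A `vocabulary`.
#' @param path File path.
#' @return `write_vocabulary`: `path`, invisibly; `read_vocabulary`: the
#'   `vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# n_train_docs=%d", vocab$n_train_docs), con)
  writeLines("term\tindex\tdf", con)
  writeLines(sprintf("%s\t%d\t%d", vocab$terms,
                     vocab$index[vocab$terms], vocab$doc_freq[vocab$terms]),
             con)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  n <- as.integer(sub("^# n_train_docs=", "", lines[1]))
  tab <- read.delim(text = lines[-1], stringsAsFactors = FALSE)
  structure(list(terms = tab$term,
                 index = setNames(tab$index, tab$term),
                 doc_freq = setNames(tab$df, tab$term),
                 n_train_docs = n),
            class = "vocabulary")
}
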
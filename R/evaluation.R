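# Confusion matrices and micro/macro-averaged precision/recall/F.  Rows of
# the confusion matrix are gold labels, columns are predictions; per-class
# tp is the diagonal, fp the column sum minus the diagonal, fn the row sum
# minus the diagonal.

#' Confusion matrix
#'
#' @param gold,pred Label vectors of equal length, all within `scheme`.
#' @param scheme A [label_scheme()] (or character vector of labels).
#' @param normalized Divide each row by its sum (rows with gold examples
#'   then sum to 1)?
#' @return A `confusion_matrix`: l x l matrix with a `scheme` attribute.
#' @examples
#' confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
#' @export
confusion_matrix <- function(gold, pred, scheme, normalized = FALSE) {
  labels <- if (inherits(scheme, "label_scheme")) scheme$labels else scheme
  if (length(gold) != length(pred)) {
    stop("gold and pred must have the same length")
  }
  bad <- setdiff(unique(c(gold, pred)), labels)
  if (length(bad)) stop("labels outside the scheme: ", paste(bad, collapse = ", "))
  m <- table(factor(gold, levels = labels), factor(pred, levels = labels))
  m <- matrix(as.integer(m), nrow = length(labels),
              dimnames = list(gold = labels, predicted = labels))
  if (normalized) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), "/")
    storage.mode(m) <- "double"
  }
  structure(m, scheme = labels, normalized = normalized,
            class = c("confusion_matrix", class(m)))
}

.cm_counts <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (isTRUE(attr(cm, "normalized"))) {
    stop("metrics require an unnormalized confusion matrix")
  }
  tp <- diag(cm)
  list(tp = tp, fp = colSums(cm) - tp, fn = rowSums(cm) - tp)
}

.prf <- function(tp, fp, fn, flag = FALSE) {
  p <- if (tp + fp > 0) tp / (tp + fp) else {
    if (flag) warning("precision 0/0 defined as 0 (no predictions for class)")
    0
  }
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

#' Per-class precision, recall, and F-score
#'
#' F is the equally weighted harmonic mean of precision and recall; 0/0
#' cells are defined as 0 (with a warning for classes never predicted).
#'
#' @param cm An unnormalized `confusion_matrix`.
#' @return Matrix with one row per class and columns `precision`, `recall`,
#'   `f`.
#' @export
per_class_metrics <- function(cm) {
  cnt <- .cm_counts(cm)
  out <- t(vapply(seq_along(cnt$tp), function(k) {
    .prf(cnt$tp[k], cnt$fp[k], cnt$fn[k], flag = TRUE)
  }, c(precision = 0, recall = 0, f = 0)))
  rownames(out) <- attr(cm, "scheme")
  out
}

#' Micro- and macro-averaged metrics report
#'
#' Micro-averages pool tp/fp/fn over classes before computing
#' precision/recall/F (for single-label prediction over the full scheme
#' this forces micro P = micro R = micro F); macro-averages are the
#' unweighted mean of the per-class values.
#'
#' @param cm An unnormalized `confusion_matrix`.
#' @return A `metrics_report`: list with `per_class`, `micro`, `macro`,
#'   `n`.
#' @export
average_metrics <- function(cm) {
  cnt <- .cm_counts(cm)
  per_class <- suppressWarnings(per_class_metrics(cm))
  micro <- .prf(sum(cnt$tp), sum(cnt$fp), sum(cnt$fn))
  macro <- colMeans(per_class)
  names(macro) <- c("precision", "recall", "f")
  structure(list(per_class = per_class, micro = micro, macro = macro,
                 n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d reports\n", x$n))
  tab <- rbind(x$per_class, micro = x$micro, macro = x$macro)
  print(round(100 * tab, 1))
  invisible(x)
}

#' Select the best configuration by micro-averaged F-score
#'
#' Ties break by macro-F, then by position in the input list.
#'
#' @param results Named list (or list with `$config`/`$metrics` entries) of
#'   `metrics_report` objects.
#' @return Index (and name, if any) of the winning configuration.
#' @export
select_best <- function(results) {
  if (length(results) == 0L) stop("no results to select from")
  micro <- vapply(results, function(r) r$micro[["f"]], numeric(1))
  macro <- vapply(results, function(r) r$macro[["f"]], numeric(1))
  best <- order(-micro, -macro, seq_along(results))[1]
  structure(best, name = names(results)[best])
}

#' Write metrics / confusion matrices as CSV
#'
#' One row per class plus `micro` and `macro` rows, values as proportions.
#'
#' @param report A `metrics_report`.
#' @param cm A `confusion_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(report, path) {
  tab <- rbind(report$per_class, micro = report$micro, macro = report$macro)
  df <- data.frame(class = rownames(tab), tab, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_confusion_csv <- function(cm, path) {
  df <- data.frame(gold = rownames(cm), as.data.frame.matrix(cm),
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
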
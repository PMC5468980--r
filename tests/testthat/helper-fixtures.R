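# Shared fixtures: tiny generator configs and corpora built in code.

# small k-class world with its own disjoint pools; separable when
# overlap = 0
tiny_config <- function(k = 3, n = 30, overlap = 0, seed = 1, ...) {
  labels <- paste0("class", seq_len(k))
  pools <- lapply(seq_len(k), function(i) paste0("term", i, letters[1:6]))
  names(pools) <- labels
  generator_config(
    label_scheme = labels,
    per_class_counts = setNames(rep(as.integer(n), k), labels),
    class_term_pools = pools,
    shared_term_pool = paste0("shared", letters[1:10]),
    overlap = overlap, cooccurrence_rate = 0,
    length_mean = 20, length_sd = 5, length_min = 5, length_max = 60,
    task = "type", source = "synthetic-tiny", seed = seed, ...)
}

tiny_corpus <- function(k = 3, n = 30, overlap = 0, seed = 1, ...) {
  corp <- generate_corpus(tiny_config(k, n, overlap, seed, ...))
  corp$incident_type <- rep(paste0("class", seq_len(k)), each = n)
  corp
}

# label-only corpus (no narratives needed) for decomposition tests
label_corpus <- function(counts) {
  labs <- rep(names(counts), counts)
  data.frame(report_id = sprintf("id%05d", seq_along(labs)),
             narrative = "x", incident_type = labs,
             severity = NA_character_, source = "synthetic-labels",
             stringsAsFactors = FALSE)
}

# train a small ensemble end to end on a separable tiny corpus
tiny_ensemble <- function(strategy = "ovso", decision = "voting", k = 3,
                          n = 20, algorithm = "logreg", weighting = "tf",
                          seed = 1) {
  corp <- tiny_corpus(k, n, overlap = 0, seed = seed)
  scheme <- label_scheme(paste0("class", seq_len(k)))
  docs <- preprocess_corpus(corp)
  labels <- setNames(corp$incident_type, corp$report_id)
  subsets <- if (strategy == "ovso") {
    decompose_ovso(scheme, corp)
  } else {
    decompose_ovsa(scheme, corp, per_class_n = n, seed = seed)
  }
  list(ensemble = train_ensemble(subsets, docs, labels, scheme, strategy,
                                 decision, algorithm, weighting),
       corpus = corp, docs = docs, labels = labels, scheme = scheme)
}

# brute-force per-report metric tally, independent of the package's
# confusion-matrix path
oracle_metrics <- function(gold, pred, labels) {
  per <- t(vapply(labels, function(k) {
    tp <- sum(gold == k & pred == k)
    fp <- sum(gold != k & pred == k)
    fn <- sum(gold == k & pred != k)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f = f)
  }, numeric(6)))
  tp <- sum(per[, "tp"]); fp <- sum(per[, "fp"]); fn <- sum(per[, "fn"])
  mp <- if (tp + fp > 0) tp / (tp + fp) else 0
  mr <- if (tp + fn > 0) tp / (tp + fn) else 0
  mf <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(per = per, micro = c(precision = mp, recall = mr, f = mf),
       macro = colMeans(per[, c("precision", "recall", "f"), drop = FALSE]))
}
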
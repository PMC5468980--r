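# Synthetic incident-report generator.  Stands in for the confidential
# hospital corpora: per-class counts follow the published balanced /
# stratified dataset compositions, report lengths follow the published
# mean/SD/range moments (truncated normal), and narratives are
# class-conditional token mixtures with a confusability knob.

# Table of dataset compositions used for training/testing designs.
# balanced: 260 per incident type, 290 per SAC level.
.strat_type_original <- c(falls = 90, medications = 68, pressure_injury = 37,
                          aggression = 49, documentation = 26,
                          blood_product = 5, patient_identification = 7,
                          infection = 6, clinical_handover = 7,
                          deteriorating_patient = 1, others = 148)
.strat_type_independent <- c(falls = 872, medications = 1053,
                             pressure_injury = 190, aggression = 487,
                             documentation = 252, blood_product = 59,
                             patient_identification = 86, infection = 22,
                             clinical_handover = 87,
                             deteriorating_patient = 14, others = 2878)
.strat_sev_original <- c(SAC1 = 25, SAC2 = 95, SAC3 = 2198, SAC4 = 2519)
.strat_sev_independent <- c(SAC1 = 23, SAC2 = 105, SAC3 = 2609, SAC4 = 3213)

# report length moments (words): state-wide system vs independent hospital
.len_statewide <- list(mean = 78.5, sd = 35.5, min = 5, max = 308)
.len_independent <- list(mean = 63.4, sd = 31.6, min = 5, max = 404)

#' Construct a synthetic-corpus generator configuration
#'
#' Most users should start from [default_config()]; this constructor
#' validates an explicit configuration.
#'
#' @param label_scheme Ordered character vector of class labels.
#' @param per_class_counts Named integer vector, label -> report count.
#' @param class_term_pools Named list, label -> character vector of
#'   discriminative terms (pairwise disjoint).
#' @param shared_term_pool Character vector of general clinical terms.
#' @param overlap Fraction in \[0,1\] of a report's tokens drawn from other
#'   classes' pools (confusability knob).
#' @param severity_keyword_pools Named list, SAC level -> indicator phrases,
#'   or `NULL` for incident-type corpora.
#' @param sac23_blend Fraction in \[0,1\] cross-mixing the SAC2/SAC3
#'   keyword pools.
#' @param cooccurrence_rate Fraction of documentation-class reports that
#'   additionally receive patient-identification or medications terms.
#' @param length_mean,length_sd,length_min,length_max Word-count model
#'   (truncated normal, rounded).
#' @param task `"type"` or `"severity"` (controls keyword injection).
#' @param source Source tag stamped on generated reports.
#' @param seed Integer master seed; per-class substreams are derived from it.
#' @return A `generator_config` object.
#' @export
generator_config <- function(label_scheme, per_class_counts, class_term_pools,
                             shared_term_pool = default_shared_pool(),
                             overlap = 0.2,
                             severity_keyword_pools = NULL,
                             sac23_blend = 0.3, cooccurrence_rate = 0.6,
                             length_mean = 78.5, length_sd = 35.5,
                             length_min = 5, length_max = 308,
                             task = c("type", "severity"),
                             source = "synthetic", seed = 1L) {
  task <- match.arg(task)
  stopifnot(length(label_scheme) >= 2L, !anyDuplicated(label_scheme))
  if (!all(names(per_class_counts) %in% label_scheme)) {
    stop("per_class_counts keys must be a subset of label_scheme")
  }
  if (any(per_class_counts < 0)) stop("per_class_counts must be >= 0")
  if (!all(names(per_class_counts) %in% names(class_term_pools))) {
    stop("every requested label needs a class term pool")
  }
  if (any(lengths(class_term_pools[names(per_class_counts)]) == 0L)) {
    stop("empty class_term_pools for a requested label")
  }
  all_terms <- unlist(class_term_pools, use.names = FALSE)
  if (anyDuplicated(all_terms)) {
    stop("class_term_pools must be pairwise disjoint")
  }
  for (x in c(overlap = overlap, sac23_blend = sac23_blend,
              cooccurrence_rate = cooccurrence_rate)) {
    if (x < 0 || x > 1) stop("rate parameters must lie in [0, 1]")
  }
  if (length_min < 1 || length_min > length_mean || length_mean > length_max) {
    stop("need length_min >= 1 and length_min <= length_mean <= length_max")
  }
  structure(list(label_scheme = label_scheme,
                 per_class_counts = per_class_counts,
                 class_term_pools = class_term_pools,
                 shared_term_pool = shared_term_pool,
                 overlap = overlap,
                 severity_keyword_pools = severity_keyword_pools,
                 sac23_blend = sac23_blend,
                 cooccurrence_rate = cooccurrence_rate,
                 length_mean = length_mean, length_sd = length_sd,
                 length_min = length_min, length_max = length_max,
                 task = task, source = source, seed = as.integer(seed)),
            class = "generator_config")
}

#' Preset generator configurations mirroring the published dataset designs
#'
#' * `balanced_type`: 260 reports for each of the 11 incident-type labels
#'   (total 2860), state-wide-system length model.
#' * `balanced_severity`: 290 reports for each of the 4 SAC levels
#'   (total 1160), state-wide-system length model.
#' * `stratified_original`: real-world class ratios of the state-wide
#'   system (type total 444, severity total 4837).
#' * `stratified_independent`: real-world class ratios of the independent
#'   hospital system (type total 6000, severity total 5950), independent
#'   length model (mean 63.4, SD 31.6, range 5-404 words).
#'
#' @param preset One of `"balanced_type"`, `"balanced_severity"`,
#'   `"stratified_original"`, `"stratified_independent"`.
#' @param seed Integer master seed.
#' @param task For the stratified presets, `"type"` or `"severity"`
#'   (the balanced presets fix the task themselves).
#' @param ... Overrides passed on to [generator_config()] (e.g. `overlap`).
#' @return A `generator_config`.
#' @examples
#' cfg <- default_config("balanced_type", seed = 7)
#' sum(cfg$per_class_counts)  # 2860
#' @export
default_config <- function(preset, seed = 1L, task = c("type", "severity"),
                           ...) {
  presets <- c("balanced_type", "balanced_severity", "stratified_original",
               "stratified_independent")
  if (length(preset) != 1L || !preset %in% presets) {
    stop("unknown preset; valid presets: ", paste(presets, collapse = ", "))
  }
  task <- match.arg(task)
  if (preset == "balanced_type") task <- "type"
  if (preset == "balanced_severity") task <- "severity"
  if (task == "type") {
    scheme <- incident_type_labels()
    pools <- default_type_pools()
    kw <- NULL
    counts <- switch(preset,
      balanced_type = setNames(rep(260L, length(scheme)), scheme),
      stratified_original = .strat_type_original,
      stratified_independent = .strat_type_independent)
  } else {
    scheme <- severity_labels()
    pools <- default_severity_pools()
    kw <- default_severity_keywords()
    counts <- switch(preset,
      balanced_severity = setNames(rep(290L, length(scheme)), scheme),
      stratified_original = .strat_sev_original,
      stratified_independent = .strat_sev_independent)
  }
  len <- if (preset == "stratified_independent") .len_independent else .len_statewide
  src <- switch(preset,
    balanced_type = "synthetic-balanced",
    balanced_severity = "synthetic-balanced",
    stratified_original = "synthetic-stratified-original",
    stratified_independent = "synthetic-stratified-independent")
  args <- list(label_scheme = scheme, per_class_counts = counts,
               class_term_pools = pools, severity_keyword_pools = kw,
               length_mean = len$mean, length_sd = len$sd,
               length_min = len$min, length_max = len$max,
               task = task, source = src, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

# truncated-normal word counts, integer-rounded, clamped by rejection
.sample_lengths <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    draw <- round(rnorm(n, mean, sd))
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  as.integer(out[seq_len(n)])
}

.substream_seed <- function(seed, j) {
  ((seed %% 1000000L) * 1009L + j * 101L) %% 2000000000L
}

.generate_class <- function(config, label, j) {
  n <- config$per_class_counts[[label]]
  if (n == 0L) return(NULL)
  set.seed(.substream_seed(config$seed, j))
  own <- config$class_term_pools[[label]]
  others <- unlist(config$class_term_pools[
    setdiff(names(config$per_class_counts), label)], use.names = FALSE)
  shared <- config$shared_term_pool
  lens <- .sample_lengths(n, config$length_mean, config$length_sd,
                          config$length_min, config$length_max)
  narratives <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    from_other <- length(others) > 0L & runif(L) < config$overlap
    from_own <- runif(L) < 0.5
    toks <- character(L)
    k_other <- sum(from_other)
    if (k_other) toks[from_other] <- sample(others, k_other, replace = TRUE)
    idx_own <- !from_other & from_own
    if (any(idx_own)) toks[idx_own] <- sample(own, sum(idx_own), replace = TRUE)
    idx_sh <- !from_other & !from_own
    if (any(idx_sh)) toks[idx_sh] <- sample(shared, sum(idx_sh), replace = TRUE)
    if (config$task == "severity" &&
        !is.null(config$severity_keyword_pools)) {
      toks <- .inject_keywords(toks, label, config)
    }
    if (config$task == "type" && label == "documentation" &&
        runif(1) < config$cooccurrence_rate) {
      toks <- .inject_cooccurrence(toks, config)
    }
    narratives[i] <- paste(toks, collapse = " ")
  }
  data.frame(report_id = sprintf("%s-%02d-%05d", config$source, j, seq_len(n)),
             narrative = narratives,
             incident_type = if (config$task == "type") label else NA_character_,
             severity = if (config$task == "severity") label else NA_character_,
             source = config$source,
             stringsAsFactors = FALSE)
}

# overwrite a random window with a multi-token indicator phrase so the word
# count is preserved; SAC2/SAC3 pools cross-mixed at rate sac23_blend
.inject_keywords <- function(toks, label, config) {
  pool_label <- label
  n_phrases <- sample(1:3, 1L)
  for (p in seq_len(n_phrases)) {
    lab <- pool_label
    if (lab %in% c("SAC2", "SAC3") && runif(1) < config$sac23_blend) {
      lab <- if (lab == "SAC2") "SAC3" else "SAC2"
    }
    pool <- config$severity_keyword_pools[[lab]]
    if (is.null(pool) || !length(pool)) next
    phrase <- strsplit(sample(pool, 1L), " ", fixed = TRUE)[[1]]
    np <- length(phrase)
    if (np > length(toks)) next
    start <- sample(seq_len(length(toks) - np + 1L), 1L)
    toks[start:(start + np - 1L)] <- phrase
  }
  toks
}

# documentation incidents co-occur with patient identification or
# medications: replace ~10% of positions (>= 2) with the secondary pool
.inject_cooccurrence <- function(toks, config) {
  secondary <- sample(c("patient_identification", "medications"), 1L)
  pool <- config$class_term_pools[[secondary]]
  if (is.null(pool)) return(toks)
  k <- max(2L, round(0.1 * length(toks)))
  k <- min(k, length(toks))
  pos <- sample(seq_along(toks), k)
  toks[pos] <- sample(pool, k, replace = TRUE)
  toks
}

#' Generate a labeled synthetic incident-report corpus
#'
#' A pure function of its configuration (including the seed): identical
#' configs yield byte-identical corpora.  Exactly `per_class_counts[k]`
#' reports carry label `k`; narratives are token mixtures of the class's
#' own pool, the shared pool, and (at rate `overlap`) other classes' pools.
#' Severity corpora additionally receive indicator phrases; see
#' [generator_config()].
#'
#' @param config A `generator_config`.
#' @return Data frame with columns `report_id`, `narrative`,
#'   `incident_type`, `severity`, `source` (one row per report).
#' @examples
#' corp <- generate_corpus(default_config("balanced_severity", seed = 3))
#' nrow(corp)  # 1160
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  labels <- names(config$per_class_counts)
  parts <- lapply(seq_along(labels), function(j) {
    .generate_class(config, labels[j], j)
  })
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Summarize a corpus (per-label counts and word-length moments)
#'
#' @param corpus Corpus data frame ([generate_corpus()] / [read_corpus()]).
#' @param label `"incident_type"`, `"severity"`, or `NULL` to auto-detect.
#' @return List with `total`, `per_label` counts, `mean_length`,
#'   `sd_length`, and `lengths_defined` (FALSE for an empty corpus).
#' @export
summarize_corpus <- function(corpus, label = NULL) {
  if (is.null(corpus) || nrow(corpus) == 0L) {
    return(list(total = 0L, per_label = integer(0), mean_length = NA_real_,
                sd_length = NA_real_, lengths_defined = FALSE))
  }
  if (is.null(label)) {
    label <- if (all(is.na(corpus$incident_type))) "severity" else "incident_type"
  }
  wc <- lengths(strsplit(trimws(corpus$narrative), "\\s+"))
  list(total = nrow(corpus),
       per_label = table(corpus[[label]]),
       mean_length = mean(wc),
       sd_length = if (length(wc) > 1L) sd(wc) else 0,
       lengths_defined = TRUE)
}

#' Write / read a corpus as JSONL or CSV
#'
#' JSONL holds one report per line with keys `report_id`, `narrative`,
#' `incident_type`, `severity`, `source` (UTF-8); CSV uses the identical
#' columns.
#'
#' @param corpus Corpus data frame.
#' @param path Output file; format inferred from the extension unless given.
#' @param format `"jsonl"` or `"csv"`.
#' @return `write_corpus`: `path`, invisibly. `read_corpus`: the corpus
#'   data frame.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  cols <- c("report_id", "narrative", "incident_type", "severity", "source")
  corpus <- corpus[, cols]
  if (format == "csv") {
    write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      writeLines(jsonlite::toJSON(as.list(corpus[i, ]), auto_unbox = TRUE,
                                  null = "null", na = "null"), con)
    }
  }
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    out <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    rows <- lapply(lines, function(l) {
      x <- jsonlite::fromJSON(l)
      x[vapply(x, is.null, logical(1))] <- NA_character_
      as.data.frame(x, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  cols <- c("report_id", "narrative", "incident_type", "severity", "source")
  stopifnot(all(cols %in% names(out)))
  out[, cols]
}
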
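# Multiclass reduction: one-versus-one (l(l-1)/2 pairwise classifiers,
# combined by voting or a decision DAG) and one-versus-all (l classifiers,
# combined by the highest calibrated probability).

#' Ordered label scheme
#'
#' The label order is fixed and persisted: it drives the DAG structure and
#' all deterministic tie-breaks.
#'
#' @param labels Character vector of at least two unique class labels.
#' @return A `label_scheme` with fields `labels` and `l`.
#' @export
label_scheme <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L || anyDuplicated(labels)) {
    stop("label scheme needs >= 2 unique, ordered labels")
  }
  structure(list(labels = labels, l = length(labels)),
            class = "label_scheme")
}

.gold <- function(corpus, scheme) {
  lab <- if (all(scheme$labels %in% corpus$incident_type)) {
    corpus$incident_type
  } else {
    corpus$severity
  }
  as.character(lab)
}

.pair_key <- function(a, b) paste(a, b, sep = "||")

#' Decompose a labeled corpus into pairwise (one-versus-one) subsets
#'
#' One subset per unordered label pair, `l(l-1)/2` in total, each holding
#' only the reports of its two labels.
#'
#' @param scheme A `label_scheme`.
#' @param corpus Corpus data frame with gold labels for the scheme.
#' @return List of subsets `list(task = list(type = "pair", a, b), ids)`.
#' @export
decompose_ovso <- function(scheme, corpus) {
  gold <- .gold(corpus, scheme)
  missing <- setdiff(scheme$labels, gold)
  if (length(missing)) {
    stop("labels missing from corpus: ", paste(missing, collapse = ", "))
  }
  labs <- scheme$labels
  subsets <- list()
  for (i in seq_len(scheme$l - 1L)) {
    for (j in seq((i + 1L), scheme$l)) {
      a <- labs[i]; b <- labs[j]
      ids <- corpus$report_id[gold %in% c(a, b)]
      subsets[[.pair_key(a, b)]] <-
        list(task = list(type = "pair", a = a, b = b), ids = ids)
    }
  }
  subsets
}

#' Decompose into one-versus-rest subsets with balanced negatives
#'
#' Each subset holds `per_class_n` positives of its target label and
#' `per_class_n` negatives sampled as evenly as possible across the other
#' `l - 1` labels: floor division, with the remainder assigned round-robin
#' in scheme order.  All draws are seeded.
#'
#' @inheritParams decompose_ovso
#' @param per_class_n Positives (and negatives) per subset, e.g. 260 for
#'   the type task or 290 for the severity task.
#' @param seed Integer seed for the negative (and positive) sampling.
#' @param exclude_ids Report ids never to sample (e.g. a frozen test set).
#' @return List of subsets `list(task = list(type = "ovr", a), ids)`.
#' @export
decompose_ovsa <- function(scheme, corpus, per_class_n, seed = 1L,
                           exclude_ids = NULL) {
  per_class_n <- as.integer(per_class_n)
  gold <- .gold(corpus, scheme)
  keep <- !(corpus$report_id %in% exclude_ids)
  ids_by_class <- split(corpus$report_id[keep], factor(gold[keep],
                                                       levels = scheme$labels))
  shortfall <- vapply(scheme$labels, function(k) {
    max(0L, per_class_n - length(ids_by_class[[k]]))
  }, integer(1))
  if (any(shortfall > 0L)) {
    stop("insufficient reports for per_class_n=", per_class_n, ": ",
         paste(sprintf("%s short by %d", names(shortfall)[shortfall > 0],
                       shortfall[shortfall > 0]), collapse = "; "))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  subsets <- list()
  for (idx in seq_along(scheme$labels)) {
    k <- scheme$labels[idx]
    set.seed(.substream_seed(as.integer(seed), idx))
    pos <- ids_by_class[[k]]
    pos <- if (length(pos) > per_class_n) sample(pos, per_class_n) else pos
    rest <- setdiff(scheme$labels, k)
    base_q <- per_class_n %/% length(rest)
    quota <- setNames(rep(base_q, length(rest)), rest)
    extra <- per_class_n %% length(rest)
    if (extra > 0L) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1L
    if (any(quota > lengths(ids_by_class[rest]))) {
      short <- quota - lengths(ids_by_class[rest])
      stop("insufficient negatives for one-vs-rest on ", k, ": ",
           paste(sprintf("%s short by %d", names(short)[short > 0],
                         short[short > 0]), collapse = "; "))
    }
    neg <- unlist(lapply(rest, function(r) {
      pool <- ids_by_class[[r]]
      if (length(pool) == quota[[r]]) pool else sample(pool, quota[[r]])
    }), use.names = FALSE)
    subsets[[k]] <- list(task = list(type = "ovr", a = k),
                         ids = c(pos, neg))
  }
  subsets
}

#' Train a binary-classifier ensemble
#'
#' One base classifier per decomposition subset.  Each base model carries
#' its own vocabulary, built from its training documents only, and its own
#' weighting.
#'
#' @param subsets Output of [decompose_ovso()] or [decompose_ovsa()].
#' @param docs Named list of preprocessed `token_doc`s (names = report id).
#' @param labels Named character vector of gold labels by report id.
#' @param scheme A `label_scheme`.
#' @param strategy `"ovso"` or `"ovsa"`.
#' @param decision `"voting"` or `"dag"` for OvsO; `"argmax_prob"` for
#'   OvsA (the DAG applies to OvsO only).
#' @param algorithm,weighting,hyperparams Passed to [train_base()] /
#'   [vectorize()]; `hyperparams` may be a single list or a per-task named
#'   list of tuned values.
#' @param calibrations Optional per-task named list of `list(scores, y)`
#'   used to Platt-calibrate SVM outputs.
#' @return An `incident_ensemble`.
#' @export
train_ensemble <- function(subsets, docs, labels, scheme,
                           strategy = c("ovso", "ovsa"),
                           decision = c("voting", "dag", "argmax_prob"),
                           algorithm = "logreg", weighting = "tf",
                           hyperparams = list(C = 1), calibrations = NULL) {
  strategy <- match.arg(strategy)
  decision <- match.arg(decision)
  if (strategy == "ovso" && !decision %in% c("voting", "dag")) {
    stop("OvsO ensembles use voting or dag decisions")
  }
  if (strategy == "ovsa" && decision != "argmax_prob") {
    stop("the DAG (and voting) decision schemes apply to OvsO only; ",
         "OvsA uses argmax_prob")
  }
  expected <- if (strategy == "ovso") scheme$l * (scheme$l - 1L) / 2L else scheme$l
  if (length(subsets) != expected) {
    stop("expected ", expected, " subsets for strategy ", strategy,
         ", got ", length(subsets))
  }
  per_task_hp <- !is.null(names(hyperparams)) &&
    all(names(hyperparams) %in% names(subsets)) &&
    length(hyperparams) == length(subsets)
  base_models <- lapply(names(subsets), function(key) {
    sub <- subsets[[key]]
    sub_docs <- docs[sub$ids]
    if (sub$task$type == "pair") {
      y <- labels[sub$ids]
      positive <- sub$task$a
    } else {
      y <- ifelse(labels[sub$ids] == sub$task$a, sub$task$a, ".rest")
      positive <- sub$task$a
    }
    vocab <- build_vocabulary(sub_docs)
    x <- vectorize(sub_docs, vocab, weighting)
    hp <- if (per_task_hp) hyperparams[[key]] else hyperparams
    model <- tryCatch(
      train_base(x, y, algorithm, hp, positive = positive, task = sub$task),
      error = function(e) {
        stop("base training failed for task ", key, ": ",
             conditionMessage(e))
      })
    model$vocab <- vocab
    model$weighting <- weighting
    if (!is.null(calibrations[[key]])) {
      model <- calibrate_model(model, calibrations[[key]]$scores,
                               calibrations[[key]]$y)
    }
    model
  })
  names(base_models) <- names(subsets)
  structure(list(scheme = scheme, strategy = strategy, decision = decision,
                 base_models = base_models, algorithm = algorithm,
                 weighting = weighting),
            class = "incident_ensemble")
}

.model_outputs <- function(model, docs) {
  x <- vectorize(docs, model$vocab, model$weighting)
  decision_and_prob(model, x)
}

#' Voting decision from pairwise outcomes (pure helper)
#'
#' Tallies one vote per contest; the label with the most votes wins.  Ties
#' break by the largest summed probability credited over the tied labels'
#' contests, then by scheme order.
#'
#' @param winners Named character vector: pair key (`"a||b"`) -> winning
#'   label.
#' @param labels Scheme labels in order.
#' @param prob_credit Optional named numeric: per label, summed calibrated
#'   probability over its contests (used only for ties).
#' @return The winning label.
#' @export
vote_decision <- function(winners, labels, prob_credit = NULL) {
  votes <- table(factor(winners, levels = labels))
  top <- labels[votes == max(votes)]
  if (length(top) == 1L) return(top)
  if (!is.null(prob_credit)) {
    cred <- prob_credit[top]
    top <- top[cred == max(cred)]
  }
  top[1]
}

#' DAG decision over an ordered candidate list (pure helper)
#'
#' Tail-rejection DDAG: the candidate list starts as the full scheme; each
#' node evaluates the (first, last) pair and rejects the loser from the
#' corresponding end, until one label remains after exactly `l - 1`
#' comparisons.
#'
#' @param labels Scheme labels in order.
#' @param decide Function `(a, b) -> winning label` for a pairwise contest.
#' @return List with `label` and `evaluations` (always `length(labels) - 1`).
#' @export
dag_decision <- function(labels, decide) {
  lo <- 1L; hi <- length(labels)
  evals <- 0L
  while (lo < hi) {
    a <- labels[lo]; b <- labels[hi]
    winner <- decide(a, b)
    evals <- evals + 1L
    if (!winner %in% c(a, b)) stop("decide() must return one of the pair")
    if (winner == a) hi <- hi - 1L else lo <- lo + 1L
  }
  list(label = labels[lo], evaluations = evals)
}

.check_fitted <- function(ensemble, strategy, decision = NULL) {
  if (!inherits(ensemble, "incident_ensemble") ||
      !length(ensemble$base_models)) {
    stop("ensemble is not fitted")
  }
  if (ensemble$strategy != strategy) {
    stop("ensemble strategy is ", ensemble$strategy, ", need ", strategy)
  }
  if (!is.null(decision) && ensemble$decision != decision) {
    stop("ensemble decision is ", ensemble$decision, ", need ", decision)
  }
}

.pair_outputs_one <- function(ensemble, tokens) {
  labs <- ensemble$scheme$labels
  doc <- list(tokens)
  out <- list()
  for (key in names(ensemble$base_models)) {
    m <- ensemble$base_models[[key]]
    o <- .model_outputs(m, doc)
    out[[key]] <- list(a = m$task$a, b = m$task$b,
                       score = o$score[1], prob = o$prob[1])
  }
  out
}

#' Predict one report with the voting scheme
#'
#' Each pairwise classifier votes by the sign of its decision score (an
#' exact 0 votes for the pair's first label).
#'
#' @param ensemble A fitted OvsO `incident_ensemble` with `decision =
#'   "voting"`.
#' @param tokens Character vector of preprocessed tokens (or a
#'   `token_doc`).
#' @return The predicted label.
#' @export
predict_voting <- function(ensemble, tokens) {
  .check_fitted(ensemble, "ovso", "voting")
  if (is.list(tokens)) tokens <- tokens$tokens
  outs <- .pair_outputs_one(ensemble, tokens)
  labs <- ensemble$scheme$labels
  winners <- vapply(outs, function(o) if (o$score >= 0) o$a else o$b,
                    character(1))
  credit <- setNames(numeric(length(labs)), labs)
  for (o in outs) {
    credit[o$a] <- credit[o$a] + o$prob
    credit[o$b] <- credit[o$b] + (1 - o$prob)
  }
  vote_decision(winners, labs, credit)
}

#' Predict one report with the DAG scheme
#'
#' Performs exactly `l - 1` base-classifier evaluations; the count is
#' attached as attribute `evaluations`.
#'
#' @inheritParams predict_voting
#' @return The predicted label with attribute `evaluations`.
#' @export
predict_dag <- function(ensemble, tokens) {
  .check_fitted(ensemble, "ovso", "dag")
  if (is.list(tokens)) tokens <- tokens$tokens
  doc <- list(tokens)
  decide <- function(a, b) {
    key <- .pair_key(a, b)
    m <- ensemble$base_models[[key]]
    if (is.null(m)) stop("missing pairwise model for ", key)
    s <- .model_outputs(m, doc)$score[1]
    if (s >= 0) m$task$a else m$task$b
  }
  res <- dag_decision(ensemble$scheme$labels, decide)
  structure(res$label, evaluations = res$evaluations)
}

#' Predict one report with the one-versus-all argmax rule
#'
#' Returns the label whose one-vs-rest classifier emits the highest
#' calibrated probability; ties break by scheme order.
#'
#' @inheritParams predict_voting
#' @return The predicted label.
#' @export
predict_ovsa <- function(ensemble, tokens) {
  .check_fitted(ensemble, "ovsa")
  if (is.list(tokens)) tokens <- tokens$tokens
  labs <- ensemble$scheme$labels
  probs <- vapply(labs, function(k) {
    .model_outputs(ensemble$base_models[[k]], list(tokens))$prob[1]
  }, numeric(1))
  labs[which.max(probs)]
}

#' Predict a corpus of preprocessed documents
#'
#' Batch prediction: each base classifier vectorizes and scores the whole
#' corpus once, then the ensemble's decision scheme is applied per
#' document.
#'
#' @param object A fitted `incident_ensemble`.
#' @param docs Named list of `token_doc`s (or token vectors).
#' @param ... Unused.
#' @return Character vector of predicted labels, one per document.
#' @export
predict.incident_ensemble <- function(object, docs, ...) {
  labs <- object$scheme$labels
  n <- length(docs)
  outs <- lapply(object$base_models, .model_outputs, docs = docs)
  if (object$strategy == "ovsa") {
    probs <- vapply(labs, function(k) outs[[k]]$prob, numeric(n))
    if (n == 1L) probs <- matrix(probs, nrow = 1, dimnames = list(NULL, labs))
    return(labs[apply(probs, 1, which.max)])
  }
  keys <- names(object$base_models)
  pair_a <- vapply(keys, function(k) object$base_models[[k]]$task$a, character(1))
  pair_b <- vapply(keys, function(k) object$base_models[[k]]$task$b, character(1))
  vapply(seq_len(n), function(d) {
    if (object$decision == "dag") {
      decide <- function(a, b) {
        key <- .pair_key(a, b)
        if (outs[[key]]$score[d] >= 0) pair_a[[key]] else pair_b[[key]]
      }
      dag_decision(labs, decide)$label
    } else {
      winners <- vapply(keys, function(k) {
        if (outs[[k]]$score[d] >= 0) pair_a[[k]] else pair_b[[k]]
      }, character(1))
      credit <- setNames(numeric(length(labs)), labs)
      for (k in keys) {
        p <- outs[[k]]$prob[d]
        credit[pair_a[[k]]] <- credit[pair_a[[k]]] + p
        credit[pair_b[[k]]] <- credit[pair_b[[k]]] + (1 - p)
      }
      vote_decision(winners, labs, credit)
    }
  }, character(1))
}
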
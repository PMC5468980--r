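# Validation protocol and factorial experiment.  A 10% test partition is
# frozen once per class (so no base classifier's training data ever touches
# any test report), then repeated random sub-sampling re-draws the 80/10
# train/validation split for tuning; final base models are refit on
# train+validation of the frozen split.

#' Repeated random sub-sampling split plan (80/10/10)
#'
#' Per class, `floor(n/10)` reports are drawn once and frozen as the test
#' set; each repetition re-draws `floor(n/10)` validation reports from the
#' remaining pool, with the rest (the remainder goes to training) used for
#' training.  All draws are seeded.
#'
#' @param corpus Corpus data frame with gold labels for the scheme.
#' @param scheme A [label_scheme()].
#' @param n_repetitions Number of train/validation repetitions (default 10).
#' @param seed Integer seed.
#' @return A `split_plan`: per-class test ids, per-repetition train and
#'   validation ids, plus flattened `test_ids`.
#' @export
make_split_plan <- function(corpus, scheme, n_repetitions = 10L, seed = 1L) {
  gold <- .gold(corpus, scheme)
  ids_by_class <- split(corpus$report_id, factor(gold, levels = scheme$labels))
  small <- names(ids_by_class)[lengths(ids_by_class) < 10L]
  if (length(small)) {
    stop("classes too small for an 80/10/10 split (need >= 10): ",
         paste(small, collapse = ", "))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  classes <- lapply(seq_along(scheme$labels), function(j) {
    k <- scheme$labels[j]
    ids <- ids_by_class[[k]]
    n <- length(ids)
    n_held <- n %/% 10L
    set.seed(.substream_seed(as.integer(seed), j))
    test <- sample(ids, n_held)
    pool <- setdiff(ids, test)
    reps <- lapply(seq_len(n_repetitions), function(r) {
      val <- sample(pool, n_held)
      list(train = setdiff(pool, val), val = val)
    })
    list(label = k, test = test, pool = pool, reps = reps)
  })
  names(classes) <- scheme$labels
  structure(list(classes = classes,
                 test_ids = unlist(lapply(classes, `[[`, "test"),
                                   use.names = FALSE),
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "split_plan")
}

.plan_rep_ids <- function(plan, r, part) {
  unlist(lapply(plan$classes, function(cl) cl$reps[[r]][[part]]),
         use.names = FALSE)
}

#' Enumerate the factorial experiment grid
#'
#' OvsO crosses with the voting and DAG decisions, OvsA with argmax only;
#' with all three algorithms and all three weightings this yields the full
#' 27-configuration factorial (18 OvsO + 9 OvsA).
#'
#' @param strategies,algorithms,weightings Character vectors.
#' @param decisions OvsO decisions to include.
#' @return Data frame with columns `strategy`, `decision`, `algorithm`,
#'   `weighting`.
#' @export
grid_configurations <- function(strategies = c("ovso", "ovsa"),
                                algorithms = .algorithms,
                                weightings = c("binary", "tf", "tfidf"),
                                decisions = c("voting", "dag")) {
  rows <- list()
  for (s in strategies) {
    decs <- if (s == "ovso") decisions else "argmax_prob"
    for (d in decs) for (a in algorithms) for (w in weightings) {
      rows[[length(rows) + 1L]] <-
        data.frame(strategy = s, decision = d, algorithm = a, weighting = w,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Experiment configuration
#'
#' @param corpus Corpus data frame (e.g. from [generate_corpus()] or
#'   [read_corpus()]).
#' @param task `"type"` or `"severity"` (selects the label scheme).
#' @param scheme Optional explicit [label_scheme()]; defaults to the task's
#'   standard scheme restricted to labels present in the corpus.
#' @param strategies,algorithms,weightings,decisions Factorial axes; see
#'   [grid_configurations()].  Invalid pairs (e.g. OvsA with DAG) error
#'   before any training.
#' @param n_repetitions Train/validation repetitions for tuning.
#' @param grids Named list algorithm -> hyperparameter grid data frame;
#'   defaults to a single-point grid `C = 1` (with a default `gamma` for
#'   the RBF kernel) — pass [default_grid()] outputs for a full search.
#' @param per_class_n Positives per OvsA subset; defaults to the smallest
#'   class count.
#' @param external Named list of additional labeled evaluation corpora.
#' @param seed Integer master seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(corpus, task = c("type", "severity"),
                              scheme = NULL,
                              strategies = c("ovso", "ovsa"),
                              algorithms = .algorithms,
                              weightings = c("binary", "tf", "tfidf"),
                              decisions = c("voting", "dag"),
                              n_repetitions = 10L, grids = NULL,
                              per_class_n = NULL, external = list(),
                              seed = 1L) {
  task <- match.arg(task)
  bad_dec <- setdiff(decisions, c("voting", "dag"))
  if (length(bad_dec)) {
    stop("invalid OvsO decision(s): ", paste(bad_dec, collapse = ", "),
         " (OvsA always uses argmax_prob; the DAG applies to OvsO only)")
  }
  stopifnot(all(strategies %in% c("ovso", "ovsa")),
            all(algorithms %in% .algorithms),
            all(weightings %in% c("binary", "tf", "tfidf")))
  if (is.null(scheme)) {
    full <- if (task == "type") incident_type_labels() else severity_labels()
    lab_col <- if (task == "type") "incident_type" else "severity"
    present <- full[full %in% unique(corpus[[lab_col]])]
    scheme <- label_scheme(present)
  }
  if (is.null(per_class_n)) {
    gold <- .gold(corpus, scheme)
    per_class_n <- min(table(factor(gold, levels = scheme$labels)))
  }
  structure(list(corpus = corpus, task = task, scheme = scheme,
                 strategies = strategies, algorithms = algorithms,
                 weightings = weightings, decisions = decisions,
                 n_repetitions = as.integer(n_repetitions), grids = grids,
                 per_class_n = as.integer(per_class_n), external = external,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

.config_grid <- function(config, algorithm) {
  g <- config$grids[[algorithm]]
  if (!is.null(g)) return(g)
  if (algorithm == "svm_rbf") {
    data.frame(C = 1, gamma = NA_real_)  # NA -> 1/ncol default at fit time
  } else {
    data.frame(C = 1, gamma = NA_real_)
  }
}

# tune (if the grid has > 1 point), calibrate, and refit one base task on
# the frozen train+validation pool
.fit_task <- function(sub, docs, labels, plan, algorithm, weighting, grid) {
  pool_ids <- setdiff(sub$ids, plan$test_ids)
  sub_docs <- docs[pool_ids]
  vocab <- build_vocabulary(sub_docs)
  x <- vectorize(sub_docs, vocab, weighting)
  if (sub$task$type == "pair") {
    y <- labels[pool_ids]
    positive <- sub$task$a
  } else {
    y <- ifelse(labels[pool_ids] == sub$task$a, sub$task$a, ".rest")
    positive <- sub$task$a
  }
  folds <- lapply(seq_len(plan$n_repetitions), function(r) {
    list(train = which(pool_ids %in% .plan_rep_ids(plan, r, "train")),
         val = which(pool_ids %in% .plan_rep_ids(plan, r, "val")))
  })
  tuned <- tune_hyperparameters(x, y, folds, algorithm, grid,
                                positive = positive)
  model <- train_base(x, y, algorithm, tuned$hyperparams,
                      positive = positive, task = sub$task)
  if (algorithm != "logreg" && length(tuned$val_scores) &&
      length(unique(tuned$val_truth)) == 2L) {
    model <- suppressWarnings(
      calibrate_model(model, tuned$val_scores, tuned$val_truth))
  }
  model$vocab <- vocab
  model$weighting <- weighting
  model$train_ids <- pool_ids
  model
}

.assemble_ensemble <- function(models, scheme, strategy, decision,
                               algorithm, weighting) {
  structure(list(scheme = scheme, strategy = strategy, decision = decision,
                 base_models = models, algorithm = algorithm,
                 weighting = weighting),
            class = "incident_ensemble")
}

#' Run the factorial experiment
#'
#' Trains every requested (strategy, decision, algorithm, weighting)
#' combination with the frozen-test / repeated sub-sampling protocol and
#' evaluates each on the frozen test partition plus any external corpora.
#' OvsO base models are shared between the voting and DAG decisions.
#' Fully reproducible from the configuration (including its seed).
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for results.csv, per-configuration
#'   confusion matrices, and a manifest.
#' @param verbose Print per-configuration progress?
#' @return List with `results` (one row per configuration: micro/macro
#'   metrics per evaluation corpus), `reports` (full `metrics_report`s and
#'   confusion matrices), `best` (configuration index by test micro-F),
#'   and `plan`.
#' @export
run_grid <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  corpus <- config$corpus
  scheme <- config$scheme
  docs <- preprocess_corpus(corpus)
  labels <- setNames(.gold(corpus, scheme), corpus$report_id)
  plan <- make_split_plan(corpus, scheme, config$n_repetitions, config$seed)
  test_docs <- docs[plan$test_ids]
  test_gold <- labels[plan$test_ids]
  ext_prep <- lapply(config$external, function(ec) {
    list(docs = preprocess_corpus(ec), gold = .gold(ec, scheme))
  })

  cfgs <- grid_configurations(config$strategies, config$algorithms,
                              config$weightings, config$decisions)
  eval_names <- c("test", names(config$external))
  reports <- vector("list", nrow(cfgs))
  rows <- vector("list", nrow(cfgs))
  trained <- list()  # cache: shared base models per (strategy, algo, weight)

  for (ci in seq_len(nrow(cfgs))) {
    cf <- cfgs[ci, ]
    cache_key <- paste(cf$strategy, cf$algorithm, cf$weighting, sep = "|")
    if (is.null(trained[[cache_key]])) {
      subsets <- if (cf$strategy == "ovso") {
        decompose_ovso(scheme, corpus)
      } else {
        # subsets follow the stated per-class sizes on the full corpus;
        # the frozen test ids are removed from each task's pool at fit time
        decompose_ovsa(scheme, corpus, config$per_class_n, seed = config$seed)
      }
      grid <- .config_grid(config, cf$algorithm)
      trained[[cache_key]] <- lapply(subsets, .fit_task, docs = docs,
                                     labels = labels, plan = plan,
                                     algorithm = cf$algorithm,
                                     weighting = cf$weighting, grid = grid)
    }
    ens <- .assemble_ensemble(trained[[cache_key]], scheme, cf$strategy,
                              cf$decision, cf$algorithm, cf$weighting)
    cfg_reports <- list()
    pred <- predict(ens, test_docs)
    cm <- confusion_matrix(test_gold, pred, scheme)
    cfg_reports$test <- list(cm = cm, report = average_metrics(cm))
    for (en in names(ext_prep)) {
      ep <- ext_prep[[en]]
      pred_e <- predict(ens, ep$docs)
      cm_e <- confusion_matrix(ep$gold, pred_e, scheme)
      cfg_reports[[en]] <- list(cm = cm_e, report = average_metrics(cm_e))
    }
    reports[[ci]] <- cfg_reports
    met <- lapply(eval_names, function(en) {
      r <- cfg_reports[[en]]$report
      setNames(c(r$micro[["f"]], r$macro[["f"]]),
               paste0(en, c("_micro_f", "_macro_f")))
    })
    rows[[ci]] <- cbind(cf, as.data.frame(as.list(unlist(met))))
    if (verbose) {
      message(sprintf("[%d/%d] %s/%s %s %s: test micro-F %.3f", ci,
                      nrow(cfgs), cf$strategy, cf$decision, cf$algorithm,
                      cf$weighting, cfg_reports$test$report$micro[["f"]]))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  best <- select_best(lapply(reports, function(r) r$test$report))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    for (ci in seq_len(nrow(cfgs))) {
      tag <- paste(cfgs[ci, ], collapse = "_")
      write_confusion_csv(reports[[ci]]$test$cm,
                          file.path(out_dir, paste0("confusion_", tag, ".csv")))
    }
    jsonlite::write_json(list(seed = config$seed,
                              n_repetitions = config$n_repetitions,
                              package_version =
                                as.character(utils::packageVersion("incidenttriage"))),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  list(results = results, reports = reports, best = best, plan = plan,
       configurations = cfgs, models = trained)
}

#' Evaluate a trained ensemble on an external labeled corpus
#'
#' The ensemble's training-time vocabularies, weighting and calibrations
#' are used unchanged (no refitting); out-of-vocabulary tokens are
#' dropped.
#'
#' @param ensemble A fitted `incident_ensemble`.
#' @param corpus Labeled corpus data frame whose labels fall within the
#'   ensemble's scheme.
#' @return List with `report` (a `metrics_report`), `cm`, and `pred`.
#' @export
evaluate_external <- function(ensemble, corpus) {
  if (is.null(corpus) || nrow(corpus) == 0L) stop("empty evaluation corpus")
  gold <- .gold(corpus, ensemble$scheme)
  unseen <- setdiff(unique(gold), ensemble$scheme$labels)
  if (length(unseen)) {
    stop("corpus labels outside the ensemble scheme: ",
         paste(unseen, collapse = ", "))
  }
  docs <- preprocess_corpus(corpus)
  pred <- predict(ensemble, docs)
  cm <- confusion_matrix(gold, pred, ensemble$scheme)
  list(report = average_metrics(cm), cm = cm, pred = pred)
}
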
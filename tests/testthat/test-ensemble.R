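# Multiclass decomposition and the three decision schemes.

test_that("OvsO decomposition yields one subset per unordered pair", {
  corp4 <- label_corpus(c(A = 5, B = 5, C = 5, D = 5))
  s4 <- decompose_ovso(label_scheme(c("A", "B", "C", "D")), corp4)
  expect_length(s4, 6L)
  corp11 <- label_corpus(setNames(rep(3, 11), incident_type_labels()))
  s11 <- decompose_ovso(label_scheme(incident_type_labels()), corp11)
  expect_length(s11, 55L)
  for (sub in s4) {
    labs <- unique(corp4$incident_type[corp4$report_id %in% sub$ids])
    expect_length(labs, 2L)
    expect_setequal(labs, c(sub$task$a, sub$task$b))
  }
  expect_error(
    decompose_ovso(label_scheme(c("A", "B", "E")), corp4), "E")
})

test_that("OvsA decomposition balances negatives evenly", {
  counts <- setNames(rep(400L, 11L), incident_type_labels())
  corp <- label_corpus(counts)
  scheme <- label_scheme(incident_type_labels())
  subs <- decompose_ovsa(scheme, corp, per_class_n = 260, seed = 3)
  expect_length(subs, 11L)
  gold <- setNames(corp$incident_type, corp$report_id)
  for (k in names(subs)) {
    tab <- table(gold[subs[[k]]$ids])
    expect_equal(unname(tab[k]), 260)
    expect_true(all(tab[setdiff(names(tab), k)] == 26))
  }
  # l = 4, per_class_n = 290: negatives 97/97/96 round-robin in label order
  corp4 <- label_corpus(setNames(rep(300L, 4L), severity_labels()))
  subs4 <- decompose_ovsa(label_scheme(severity_labels()), corp4,
                          per_class_n = 290, seed = 3)
  gold4 <- setNames(corp4$incident_type, corp4$report_id)
  tab <- table(gold4[subs4$SAC3$ids])
  expect_equal(unname(tab[c("SAC1", "SAC2", "SAC4")]), c(97, 97, 96),
               ignore_attr = TRUE)
  # seeded: same seed reproduces the sampled subsets exactly
  subs4b <- decompose_ovsa(label_scheme(severity_labels()), corp4,
                           per_class_n = 290, seed = 3)
  expect_identical(subs4, subs4b)
  expect_error(decompose_ovsa(label_scheme(severity_labels()), corp4,
                              per_class_n = 301), "short by")
})

test_that("train_ensemble enforces the strategy/decision contract", {
  fx <- tiny_ensemble("ovso", "voting", k = 4, n = 12)
  expect_length(fx$ensemble$base_models, 6L)
  fx2 <- tiny_ensemble("ovsa", "argmax_prob", k = 4, n = 12)
  expect_length(fx2$ensemble$base_models, 4L)
  subsets <- decompose_ovsa(fx$scheme, fx$corpus, per_class_n = 12)
  expect_error(
    train_ensemble(subsets, fx$docs, fx$labels, fx$scheme, "ovsa", "dag"),
    "OvsO only")
  expect_error(
    train_ensemble(subsets[-1], fx$docs, fx$labels, fx$scheme, "ovsa",
                   "argmax_prob"),
    "expected 4")
})

test_that("voting tallies pairwise outcomes", {
  labs <- c("A", "B", "C", "D")
  # A beats everyone, B beats C and D, C beats D -> A on 3 votes
  winners <- c("A||B" = "A", "A||C" = "A", "A||D" = "A",
               "B||C" = "B", "C||D" = "C", "B||D" = "B")
  expect_equal(vote_decision(winners, labs), "A")
  # engineered 3-way tie (A>B, B>C, C>A; D loses all): prob credit decides
  winners2 <- c("A||B" = "A", "A||C" = "C", "A||D" = "A",
                "B||C" = "B", "C||D" = "C", "B||D" = "B")
  credit <- c(A = 1.9, B = 2.1, C = 2.0, D = 0)
  expect_equal(vote_decision(winners2, labs, credit), "B")
  # equal credit -> scheme order
  expect_equal(vote_decision(winners2, labs, c(A = 1, B = 1, C = 1, D = 0)),
               "A")
  # trained separable ensemble recovers gold via voting
  fx <- tiny_ensemble("ovso", "voting", k = 4, n = 12)
  probe <- fx$docs[seq(1, length(fx$docs), 7)]
  pred <- vapply(probe, function(d) predict_voting(fx$ensemble, d),
                 character(1))
  expect_equal(unname(pred), unname(fx$labels[names(probe)]))
})

test_that("DAG traversal rejects from the ends in l-1 comparisons", {
  # severity scheme walk-through: root (SAC1, SAC4); rejecting SAC4 then
  # SAC1 lands in node (SAC2, SAC3)
  visited <- list()
  decide <- function(a, b) {
    visited[[length(visited) + 1L]] <<- c(a, b)
    c("SAC1|SAC4" = "SAC1", "SAC1|SAC3" = "SAC3",
      "SAC2|SAC3" = "SAC3")[paste(a, b, sep = "|")]
  }
  res <- dag_decision(severity_labels(), decide)
  expect_equal(res$label, "SAC3")
  expect_equal(res$evaluations, 3L)
  expect_equal(visited,
               list(c("SAC1", "SAC4"), c("SAC1", "SAC3"),
                    c("SAC2", "SAC3")))
  # trained ensemble: evaluation counter reads exactly l - 1
  fx <- tiny_ensemble("ovso", "dag", k = 4, n = 12)
  pred <- predict_dag(fx$ensemble, fx$docs[[1]])
  expect_equal(attr(pred, "evaluations"), 3L)
  expect_equal(as.character(pred), fx$labels[[1]])
})

test_that("OvsA prediction is the argmax of calibrated probabilities", {
  fx <- tiny_ensemble("ovsa", "argmax_prob", k = 3, n = 12)
  probe <- fx$docs[seq(1, length(fx$docs), 5)]
  for (d in probe) {
    pred <- predict_ovsa(fx$ensemble, d)
    # independent brute-force max over the probability list
    probs <- vapply(fx$scheme$labels, function(k) {
      m <- fx$ensemble$base_models[[k]]
      v <- vectorize(list(d), m$vocab, m$weighting)
      decision_and_prob(m, v)$prob[1]
    }, numeric(1))
    expect_equal(pred, names(probs)[which.max(probs)])
  }
})

test_that("batch prediction agrees with per-document prediction", {
  for (dec in c("voting", "dag")) {
    fx <- tiny_ensemble("ovso", dec, k = 3, n = 12)
    probe <- fx$docs[seq(1, length(fx$docs), 4)]
    batch <- predict(fx$ensemble, probe)
    single <- vapply(probe, function(d) {
      if (dec == "dag") as.character(predict_dag(fx$ensemble, d))
      else predict_voting(fx$ensemble, d)
    }, character(1))
    expect_equal(unname(batch), unname(single))
  }
})

test_that("unfitted ensembles and missing models error", {
  fx <- tiny_ensemble("ovso", "voting", k = 3, n = 12)
  empty <- structure(list(scheme = fx$scheme, strategy = "ovso",
                          decision = "voting", base_models = list()),
                     class = "incident_ensemble")
  expect_error(predict_voting(empty, fx$docs[[1]]), "not fitted")
  broken <- fx$ensemble
  broken$decision <- "dag"
  broken$base_models[["class1||class3"]] <- NULL
  expect_error(predict_dag(broken, fx$docs[[1]]), "missing pairwise")
})

test_that("ensemble bundles round-trip through save/load", {
  fx <- tiny_ensemble("ovso", "voting", k = 3, n = 12)
  dir <- withr::local_tempdir()
  save_ensemble(fx$ensemble, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_ensemble(dir)
  probe <- fx$docs[seq(1, length(fx$docs), 5)]
  expect_identical(predict(back, probe), predict(fx$ensemble, probe))
  expect_identical(back$scheme$labels, fx$scheme$labels)
})
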
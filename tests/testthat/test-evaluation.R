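# Confusion matrices, per-class metrics, micro/macro averaging, selection.

test_that("confusion_matrix counts gold-by-predicted cells", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(gold = c("A", "B"),
                                                   predicted = c("A", "B"))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 3)
  perfect <- confusion_matrix(c("A", "B", "C"), c("A", "B", "C"),
                              c("A", "B", "C"))
  expect_true(all(unclass(perfect) == diag(3)))
  norm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"),
                           normalized = TRUE)
  expect_equal(unname(rowSums(norm)), c(1, 1), tolerance = 1e-9)
  expect_error(confusion_matrix("A", c("A", "B"), c("A", "B")),
               "same length")
  expect_error(confusion_matrix("A", "Z", c("A", "B")), "outside")
})

test_that("per-class metrics follow the harmonic-mean definition", {
  # tp=8, fp=2, fn=2 for class A
  gold <- c(rep("A", 10), rep("B", 10))
  pred <- c(rep("A", 8), "B", "B", "A", "A", rep("B", 8))
  cm <- confusion_matrix(gold, pred, c("A", "B"))
  m <- per_class_metrics(cm)
  expect_equal(unname(m["A", ]), c(0.8, 0.8, 0.8))
  # never-predicted class: 0/0 defined as 0, with a warning flag
  cm0 <- confusion_matrix(c("A", "A", "B", "B", "B"),
                          c("B", "B", "B", "B", "B"), c("A", "B"))
  expect_warning(m0 <- per_class_metrics(cm0), "0/0")
  expect_equal(unname(m0["A", ]), c(0, 0, 0))
  # P=1, R=0.5 -> F = 2/3
  cmh <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(per_class_metrics(cmh)["A", "f"], 2 / 3)
  expect_error(per_class_metrics(
    confusion_matrix("A", "A", c("A", "B"), normalized = TRUE)),
    "unnormalized")
})

test_that("micro and macro averages obey their identities", {
  set.seed(10)
  labs <- c("A", "B", "C")
  gold <- sample(labs, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, gold, sample(labs, 60, replace = TRUE))
  cm <- confusion_matrix(gold, pred, labs)
  rep_ <- average_metrics(cm)
  # micro P = R = F for complete single-label predictions
  expect_equal(rep_$micro[["precision"]], rep_$micro[["recall"]],
               tolerance = 1e-12)
  expect_equal(rep_$micro[["precision"]], rep_$micro[["f"]],
               tolerance = 1e-12)
  # macro-F is the unweighted mean of per-class F
  expect_equal(rep_$macro[["f"]], mean(rep_$per_class[, "f"]))
  # conservation
  expect_equal(sum(diag(cm)), sum(gold == pred))
  expect_equal(unname(rowSums(cm)),
               as.numeric(table(factor(gold, levels = labs))))
  # worked example: engineered F-scores 0.8 (A) and 0.4 (B) average to 0.6
  gold2 <- c(rep("A", 10), rep("B", 5), rep("C", 6))
  pred2 <- c(rep("A", 8), "B", "B", "A", "A", "B", "B", "C",
             rep("C", 5), "B")
  fake <- confusion_matrix(gold2, pred2, c("A", "B", "C"))
  pc <- per_class_metrics(fake)
  expect_equal(unname(pc["A", "f"]), 0.8)
  expect_equal(unname(pc["B", "f"]), 0.4)
  expect_equal(mean(pc[c("A", "B"), "f"]), 0.6)
})

test_that("metrics agree with the brute-force tally oracle", {
  set.seed(11)
  for (i in 1:20) {
    labs <- LETTERS[seq_len(sample(2:5, 1))]
    n <- sample(5:40, 1)
    gold <- sample(labs, n, replace = TRUE)
    pred <- sample(labs, n, replace = TRUE)
    cm <- confusion_matrix(gold, pred, labs)
    got <- suppressWarnings(average_metrics(cm))
    want <- oracle_metrics(gold, pred, labs)
    expect_equal(got$micro[["f"]], unname(want$micro["f"]), tolerance = 1e-12)
    expect_equal(unname(got$macro), unname(want$macro), tolerance = 1e-12)
    expect_equal(unname(got$per_class[, "f"]), unname(want$per[, "f"]),
                 tolerance = 1e-12)
  }
})

test_that("select_best maximizes micro-F with macro-F tie-break", {
  mk <- function(micro, macro) {
    structure(list(micro = c(precision = micro, recall = micro, f = micro),
                   macro = c(precision = macro, recall = macro, f = macro)),
              class = "metrics_report")
  }
  expect_equal(as.integer(select_best(list(mk(0.70, 0.7), mk(0.78, 0.5)))),
               2L)
  expect_equal(as.integer(select_best(list(mk(0.7, 0.5), mk(0.7, 0.6)))), 2L)
  expect_equal(as.integer(select_best(list(mk(0.7, 0.5)))), 1L)
  expect_equal(as.integer(select_best(list(mk(0.7, 0.5), mk(0.7, 0.5)))), 1L)
  expect_error(select_best(list()), "no results")
})

test_that("metrics and confusion matrices export as CSV", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  rep_ <- average_metrics(cm)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics_csv(rep_, p1)
  write_confusion_csv(cm, p2)
  tab <- read.csv(p1)
  expect_equal(tab$class, c("A", "B", "micro", "macro"))
  expect_equal(read.csv(p2)$gold, c("A", "B"))
})
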
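# Base binary classifiers: training, decision/probability contract, tuning.

make_clouds <- function(n = 20, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), n), matrix(rnorm(2 * n, gap), n))
  list(x = Matrix::Matrix(x, sparse = TRUE), y = rep(c("pos", "neg"), each = n))
}

# fixed 4-cluster XOR fixture
make_xor <- function(n = 20, seed = 2) {
  set.seed(seed)
  x <- matrix(c(rnorm(n, 0, .2), rnorm(n, 3, .2), rnorm(n, 0, .2),
                rnorm(n, 3, .2),
                rnorm(n, 0, .2), rnorm(n, 3, .2), rnorm(n, 3, .2),
                rnorm(n, 0, .2)), ncol = 2)
  list(x = Matrix::Matrix(x, sparse = TRUE), y = rep(c("P", "P", "N", "N"), each = n))
}

test_that("all algorithms separate well-separated clouds", {
  d <- make_clouds()
  for (alg in c("logreg", "svm_linear", "svm_rbf")) {
    m <- train_base(d$x, d$y, alg, list(C = 1, gamma = 0.5),
                    positive = "pos")
    acc <- mean((decision_score(m, d$x) > 0) == (d$y == "pos"))
    expect_equal(acc, 1, info = alg)
  }
})

test_that("RBF kernel solves XOR where the linear SVM cannot", {
  d <- make_xor()
  ml <- train_base(d$x, d$y, "svm_linear", list(C = 1), positive = "P")
  mr <- train_base(d$x, d$y, "svm_rbf", list(C = 10, gamma = 1),
                   positive = "P")
  acc_lin <- mean((decision_score(ml, d$x) > 0) == (d$y == "P"))
  acc_rbf <- mean((decision_score(mr, d$x) > 0) == (d$y == "P"))
  expect_lte(acc_lin, 0.75)
  expect_equal(acc_rbf, 1)
})

test_that("degenerate inputs raise errors", {
  d <- make_clouds()
  expect_error(train_base(d$x, rep("pos", nrow(d$x))), "two classes")
  expect_error(train_base(d$x, d$y[-1]), "dimension mismatch")
  expect_error(train_base(d$x, d$y, "nnet"), "unknown algorithm")
  expect_error(train_base(d$x, d$y, "logreg", list(C = -1)), "positive")
  m <- train_base(d$x, d$y, "logreg", positive = "pos")
  expect_error(decision_score(m, d$x[, 1, drop = FALSE]), "dimension")
  expect_error(decision_score(structure(list(), class = "base_classifier"),
                              d$x), "not a fitted")
})

test_that("probability contract: logreg sigmoid, calibration monotone", {
  d <- make_clouds(gap = 2)
  m <- train_base(d$x, d$y, "logreg", list(C = 1), positive = "pos")
  out <- decision_and_prob(m, d$x)
  # logreg prob is exactly the sigmoid of w.x + b
  expect_equal(out$prob, plogis(as.numeric(as.matrix(d$x) %*% m$fit$w) +
                                  m$fit$b))
  # symmetric calibration maps score 0 to prob 0.5
  msvm <- train_base(d$x, d$y, "svm_linear", list(C = 1), positive = "pos")
  msvm$calibration <- list(a = 1, c = 0)
  grid0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                dims = c(1, ncol(d$x)))
  s0 <- decision_score(msvm, grid0)
  p0 <- decision_and_prob(msvm, grid0)$prob
  expect_equal(p0, plogis(s0))
  # calibrated probs are order-isomorphic to scores
  sc <- decision_score(msvm, d$x)
  mc <- calibrate_model(msvm, sc, d$y == "pos")
  expect_gt(mc$calibration$a, 0)
  pr <- decision_and_prob(mc, d$x)$prob
  expect_false(is.unsorted(pr[order(sc)]))
})

test_that("retraining with identical inputs reproduces predictions", {
  d <- make_clouds(gap = 1.5, seed = 5)
  probe <- d$x[seq(1, 40, 3), ]
  for (alg in c("logreg", "svm_rbf")) {
    m1 <- train_base(d$x, d$y, alg, list(C = 2, gamma = 0.25),
                     positive = "pos")
    m2 <- train_base(d$x, d$y, alg, list(C = 2, gamma = 0.25),
                     positive = "pos")
    expect_identical(decision_score(m1, probe), decision_score(m2, probe))
  }
})

test_that("tuning selects by mean validation F with deterministic ties", {
  d <- make_clouds(n = 30, gap = 3, seed = 7)
  folds <- list(list(train = c(1:20, 31:50), val = c(21:30, 51:60)),
                list(train = c(11:30, 41:60), val = c(1:10, 31:40)))
  # separable: every C attains F 1.0 -> tie broken toward smallest C
  tuned <- tune_hyperparameters(d$x, d$y, folds, "logreg",
                                grid = data.frame(C = c(4, 1, 16),
                                                  gamma = NA),
                                positive = "pos")
  expect_equal(tuned$hyperparams$C, 1)
  expect_equal(tuned$mean_f, 1)
  # mean F equals the hand-averaged per-repetition F on a 2-rep fixture
  set.seed(8)
  noisy_y <- d$y
  flip <- sample(length(noisy_y), 12)
  noisy_y[flip] <- ifelse(noisy_y[flip] == "pos", "neg", "pos")
  tuned2 <- tune_hyperparameters(d$x, noisy_y, folds, "logreg",
                                 grid = data.frame(C = 1, gamma = NA),
                                 positive = "pos")
  f_by_hand <- vapply(folds, function(fold) {
    m <- train_base(d$x[fold$train, ], noisy_y[fold$train], "logreg",
                    list(C = 1), positive = "pos")
    pred <- decision_score(m, d$x[fold$val, ]) > 0
    truth <- noisy_y[fold$val] == "pos"
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, numeric(1))
  expect_equal(unname(tuned2$table[1, "mean_f"]), mean(f_by_hand))
  # default grids follow the standard log spacing
  expect_equal(nrow(default_grid("logreg")), 11L)
  expect_equal(nrow(default_grid("svm_rbf")), 110L)
})
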
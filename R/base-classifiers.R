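# Binary base classifiers behind a common decision-score / probability
# contract: L2-regularized logistic regression (glmnet ridge; lambda =
# 1/(n*C) so larger C means weaker regularization, as for the SVMs), and
# linear / RBF-kernel SVMs solved by the built-in SMO optimizer.

.algorithms <- c("logreg", "svm_linear", "svm_rbf")

.row_norms2 <- function(x) Matrix::rowSums(x^2)

.kernel_matrix <- function(x1, x2, algorithm, gamma) {
  lin <- as.matrix(x1 %*% Matrix::t(x2))
  if (algorithm == "svm_linear") return(lin)
  d2 <- outer(.row_norms2(x1), .row_norms2(x2), "+") - 2 * lin
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Train a binary base classifier
#'
#' @param features Sparse feature matrix (documents x terms), e.g. from
#'   [vectorize()].
#' @param labels Vector of two distinct class labels, one per row.
#' @param algorithm `"logreg"`, `"svm_linear"`, or `"svm_rbf"`.
#' @param hyperparams List with `C` (positive trade-off; default 1) and,
#'   for the RBF kernel, `gamma` (positive width; default `1/ncol`).
#' @param positive Label treated as the positive class (decision score
#'   > 0); defaults to the first label in sort order.
#' @param task Optional task descriptor (`list(type = "pair", a =, b =)` or
#'   `list(type = "ovr", a =)`) stored on the model.
#' @param tol,max_iter Solver controls; non-convergence raises a warning.
#' @return A `base_classifier` object.
#' @export
train_base <- function(features, labels, algorithm = "logreg",
                       hyperparams = list(C = 1), positive = NULL,
                       task = NULL, tol = 1e-4, max_iter = 200000L) {
  if (!algorithm %in% .algorithms) {
    stop("unknown algorithm; valid: ", paste(.algorithms, collapse = ", "))
  }
  if (nrow(features) != length(labels)) {
    stop("dimension mismatch: ", nrow(features), " rows vs ",
         length(labels), " labels")
  }
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) {
    stop("need exactly two classes in labels, got ", length(classes))
  }
  if (is.null(positive)) positive <- classes[1]
  if (!positive %in% classes) stop("positive label not present in labels")
  C <- hyperparams$C %||% 1
  if (C <= 0) stop("C must be positive")
  y <- ifelse(as.character(labels) == positive, 1, -1)
  x <- as(features, "CsparseMatrix")

  fit <- switch(algorithm,
    logreg = {
      lam <- 1 / (nrow(x) * C)
      gm <- glmnet::glmnet(x, factor(y, levels = c(-1, 1)),
                           family = "binomial", alpha = 0,
                           lambda = lam * c(100, 10, 1),
                           standardize = FALSE, thresh = 1e-8)
      cf <- as.matrix(glmnet::coef.glmnet(gm, s = lam))
      list(w = cf[-1, 1], b = cf[1, 1])
    },
    {
      gamma <- hyperparams$gamma %||% (1 / ncol(x))
      if (algorithm == "svm_rbf" && gamma <= 0) stop("gamma must be positive")
      K <- .kernel_matrix(x, x, algorithm, gamma)
      sol <- smo_solve(K, y, C, eps = tol, max_iter = max_iter)
      if (!sol$converged) {
        warning("SMO did not converge within ", max_iter, " iterations")
      }
      sv <- which(sol$alpha > 1e-8)
      list(sv_x = x[sv, , drop = FALSE],
           sv_coef = sol$alpha[sv] * y[sv],
           b = sol$b, gamma = gamma)
    })

  structure(list(task = task, algorithm = algorithm,
                 hyperparams = list(C = C, gamma = hyperparams$gamma),
                 positive = positive, negative = setdiff(classes, positive),
                 n_features = ncol(x), fit = fit, calibration = NULL),
            class = "base_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decision scores of a base classifier
#'
#' @param model A fitted `base_classifier`.
#' @param x Sparse feature matrix with the model's feature dimension.
#' @return Numeric vector of real-valued scores (positive favors the
#'   model's positive class).
#' @export
decision_score <- function(model, x) {
  if (!inherits(model, "base_classifier") || is.null(model$fit)) {
    stop("model is not a fitted base_classifier")
  }
  if (ncol(x) != model$n_features) {
    stop("dimension mismatch: model expects ", model$n_features, " features")
  }
  x <- as(x, "CsparseMatrix")
  if (model$algorithm == "logreg") {
    drop(as.matrix(x %*% model$fit$w)) + model$fit$b
  } else {
    K <- .kernel_matrix(x, model$fit$sv_x, model$algorithm, model$fit$gamma)
    drop(K %*% model$fit$sv_coef) + model$fit$b
  }
}

#' Decision score and calibrated probability
#'
#' Logistic regression emits its native sigmoid probability; SVM scores are
#' mapped through a Platt-style logistic calibration fitted on
#' validation-fold scores (identity calibration `plogis(score)` until
#' [calibrate_model()] is applied).  Probabilities refer to the model's
#' positive class and are monotone nondecreasing in the score.
#'
#' @inheritParams decision_score
#' @return List with numeric vectors `score` and `prob`.
#' @export
decision_and_prob <- function(model, x) {
  s <- decision_score(model, x)
  p <- if (model$algorithm == "logreg") {
    plogis(s)
  } else if (!is.null(model$calibration)) {
    plogis(model$calibration$a * s + model$calibration$c)
  } else {
    plogis(s)
  }
  list(score = s, prob = p)
}

#' Fit Platt-style sigmoid calibration from held-out scores
#'
#' Newton optimization of the two-parameter sigmoid
#' `P(y = 1 | s) = plogis(a * s + c)` with the usual smoothed targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`.  The slope is clamped to be
#' nonnegative so calibrated probabilities stay order-isomorphic to scores.
#'
#' @param scores Decision scores on held-out (validation) data.
#' @param y Logical/0-1 vector: is the positive class the truth?
#' @return List with slope `a` and offset `c`.
#' @export
fit_platt <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  t_hi <- (n_pos + 1) / (n_pos + 2)
  t_lo <- 1 / (n_neg + 2)
  targ <- ifelse(y == 1, t_hi, t_lo)
  # minimize NLL over (A, B) for p = plogis(A*s + B)
  A <- 0; B <- log((n_neg + 1) / (n_pos + 1)) * -1
  for (it in 1:100) {
    z <- A * scores + B
    p <- plogis(z)
    g_A <- sum((p - targ) * scores)
    g_B <- sum(p - targ)
    w <- p * (1 - p)
    h_AA <- sum(w * scores^2) + 1e-12
    h_AB <- sum(w * scores)
    h_BB <- sum(w) + 1e-12
    det <- h_AA * h_BB - h_AB^2
    if (abs(det) < 1e-20) break
    d_A <- (h_BB * g_A - h_AB * g_B) / det
    d_B <- (h_AA * g_B - h_AB * g_A) / det
    A <- A - d_A
    B <- B - d_B
    if (max(abs(d_A), abs(d_B)) < 1e-10) break
  }
  if (A < 0) {
    warning("calibration slope was negative; clamped to preserve ",
            "monotonicity in the decision score")
    A <- 1e-6
  }
  list(a = A, c = B)
}

#' Attach calibration parameters to a fitted model
#'
#' @param model A `base_classifier`.
#' @param scores,y Held-out scores and positive-class indicators passed to
#'   [fit_platt()].
#' @return The model with `calibration` set.
#' @export
calibrate_model <- function(model, scores, y) {
  model$calibration <- fit_platt(scores, y)
  model
}

#' Default hyperparameter grids
#'
#' Standard log-spaced grids: `C` over `2^(-5), 2^(-3), ..., 2^15` and, for
#' the RBF kernel, `gamma` over `2^(-15), 2^(-13), ..., 2^3`.
#'
#' @param algorithm Base-classifier algorithm name.
#' @return Data frame with columns `C` and `gamma` (`NA` when unused).
#' @export
default_grid <- function(algorithm = .algorithms) {
  algorithm <- match.arg(algorithm)
  Cs <- 2^seq(-5, 15, by = 2)
  if (algorithm == "svm_rbf") {
    expand.grid(C = Cs, gamma = 2^seq(-15, 3, by = 2))
  } else {
    data.frame(C = Cs, gamma = NA_real_)
  }
}

.binary_f1 <- function(pred_pos, true_pos) {
  tp <- sum(pred_pos & true_pos)
  fp <- sum(pred_pos & !true_pos)
  fn <- sum(!pred_pos & true_pos)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

#' Tune hyperparameters by mean validation F-score
#'
#' Each grid point is trained on every (train, validation) repetition; the
#' point maximizing the mean validation F-score of the task's positive
#' class wins.  Ties break toward smaller `C`, then smaller `gamma`.
#' Grid points that fail to train on any fold are skipped with a warning;
#' if all fail, an error is raised.
#'
#' @param features,labels Full design for the binary task.
#' @param folds List of repetitions, each `list(train = idx, val = idx)`.
#' @param algorithm Base-classifier algorithm.
#' @param grid Data frame of candidate `C` (and `gamma`) values.
#' @param positive Positive-class label (default: first in sort order).
#' @return List with `hyperparams` (best point), `mean_f`, the score
#'   `table`, and `val_scores`/`val_truth` collected at the best point for
#'   downstream calibration.
#' @export
tune_hyperparameters <- function(features, labels, folds,
                                 algorithm = "logreg",
                                 grid = default_grid(algorithm),
                                 positive = NULL) {
  stopifnot(nrow(grid) >= 1L, length(folds) >= 1L)
  if (is.null(positive)) positive <- sort(unique(as.character(labels)))[1]
  res <- rep(NA_real_, nrow(grid))
  cache <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hp <- list(C = grid$C[g],
               gamma = if ("gamma" %in% names(grid) && !is.na(grid$gamma[g]))
                 grid$gamma[g] else NULL)
    fs <- numeric(0)
    scores <- truth <- numeric(0)
    ok <- TRUE
    for (fold in folds) {
      fit <- tryCatch(
        train_base(features[fold$train, , drop = FALSE], labels[fold$train],
                   algorithm, hp, positive = positive),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("grid point C=", hp$C, " failed on a fold: ",
                conditionMessage(fit))
        ok <- FALSE
        break
      }
      s <- decision_score(fit, features[fold$val, , drop = FALSE])
      tr <- as.character(labels[fold$val]) == positive
      fs <- c(fs, .binary_f1(s > 0, tr))
      scores <- c(scores, s)
      truth <- c(truth, tr)
    }
    if (ok) {
      res[g] <- mean(fs)
      cache[[g]] <- list(scores = scores, truth = truth)
    }
  }
  if (all(is.na(res))) stop("all grid points failed to train")
  # max mean F; ties -> smaller C, then smaller gamma
  ord <- order(-res, grid$C, if ("gamma" %in% names(grid)) grid$gamma else
               seq_len(nrow(grid)), na.last = TRUE)
  best <- ord[1]
  list(hyperparams = list(C = grid$C[best],
                          gamma = if ("gamma" %in% names(grid) &&
                                      !is.na(grid$gamma[best]))
                            grid$gamma[best] else NULL),
       mean_f = res[best],
       table = cbind(grid, mean_f = res),
       val_scores = cache[[best]]$scores,
       val_truth = cache[[best]]$truth)
}
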
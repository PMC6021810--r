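# Evaluation protocol: deterministic DUPLEX 2:1 train/test split,
# leave-one-out cross-validated grid search for each classifier's
# hyper-parameters, and overall/per-class accuracy reporting.

#' Default hyper-parameter grids
#'
#' The stock search spaces: `k` odd in 1--49 for k-NN; latent variables
#' 1--10 for the PLS family; penalty `C` in 1--8 for the SVM; Gaussian
#' width `sigma` on a log scale over 1e-3--1e3 (7 decade points);
#' localization `phi` in 0.1--25.
#'
#' @param algorithm One of `"knn"`, `"svm"`, `"plsda"`, `"kplsda"`,
#'   `"lwplsc"`.
#' @return Named list of parameter value vectors.
#' @export
default_param_grid <- function(algorithm = c("knn", "svm", "plsda", "kplsda",
                                             "lwplsc")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         knn = list(k = seq(1L, 49L, by = 2L)),
         svm = list(C = 1:8),
         plsda = list(n_lv = 1:10),
         kplsda = list(n_lv = 1:10, sigma = 10^seq(-3, 3)),
         lwplsc = list(n_lv = 1:10, phi = c(0.1, 0.5, 1, 2, 5, 10, 15, 20, 25)))
}

#' Deterministic DUPLEX train/test split
#'
#' Repeatedly locates the pair of still-unassigned samples with the largest
#' Euclidean inter-point distance and assigns the pair to the training and
#' test sets in alternation (training first), until the smaller set's quota
#' is filled; all remaining samples then go to the larger set. This keeps
#' the diversity of the full data in both sets and involves no randomness.
#'
#' The integer split rule: `n_test = floor(n * r2 / (r1 + r2))`,
#' `n_train = n - n_test` for `ratio = c(r1, r2)`. If a set has exactly one
#' free slot, the lower-index point of the selected pair fills it and the
#' other point returns to the pool.
#'
#' @param X `n x p` matrix or `feature_matrix`.
#' @param ratio Two positive integers, train : test (default 2:1).
#' @return List of class `duplex_split` with sorted `train_idx` and
#'   `test_idx`.
#' @export
duplex_split <- function(X, ratio = c(2, 1)) {
  if (inherits(X, "feature_matrix")) X <- X$X
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(ratio) != 2L || any(ratio <= 0))
    rc_error("invalid_parameter", "ratio must be two positive numbers")
  n_test <- floor(n * ratio[2] / sum(ratio))
  n_train <- n - n_test
  if (n < 4L || n_test < 1L || n_train < 2L)
    rc_error("invalid_parameter", "too few samples for the requested split ratio")
  D <- as.matrix(stats::dist(X))
  remaining <- seq_len(n)
  train <- integer(0); test <- integer(0)
  take_train <- TRUE
  while (length(remaining) > 0L) {
    if (length(test) >= n_test) { train <- c(train, remaining); break }
    if (length(train) >= n_train) { test <- c(test, remaining); break }
    Dr <- D[remaining, remaining, drop = FALSE]
    idx <- which(Dr == max(Dr), arr.ind = TRUE)[1L, ] # deterministic first hit
    pair <- sort(remaining[idx])
    quota <- if (take_train) n_train - length(train) else n_test - length(test)
    picked <- if (quota >= 2L) pair else pair[1L]
    if (take_train) train <- c(train, picked) else test <- c(test, picked)
    remaining <- setdiff(remaining, picked)
    take_train <- !take_train
  }
  structure(list(train_idx = sort(train), test_idx = sort(test)),
            class = "duplex_split")
}

# Single fit/predict dispatch shared by LOOCV and final evaluation.
fit_predict_labels <- function(algorithm, X_tr, y_tr, X_te, params) {
  switch(algorithm,
    knn = knn_predict(X_tr, y_tr, X_te, k = params$k),
    svm = svm_predict(svm_fit(X_tr, y_tr, C = params$C,
                              kernel = params$kernel %||% "puk",
                              puk_omega = params$puk_omega %||% 1,
                              puk_sigma = params$puk_sigma %||% 1), X_te)$labels,
    plsda = suppressWarnings(
      pls_predict(pls_fit(X_tr, y_tr, n_lv = params$n_lv), X_te)$labels),
    kplsda = suppressWarnings(
      kpls_predict(kpls_fit(X_tr, y_tr, n_lv = params$n_lv,
                            sigma = params$sigma), X_te)$labels),
    lwplsc = lwplsc_predict(X_tr, y_tr, X_te, phi = params$phi,
                            n_lv = params$n_lv)$labels,
    rc_error("invalid_parameter", paste("unknown algorithm:", algorithm)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out cross-validated accuracy
#'
#' Each sample in turn is held out, the classifier is fitted on the
#' remaining `n - 1` samples (for the locally weighted classifier the
#' held-out sample is predicted just-in-time) and the held-out sample is
#' predicted. A classifier failure on a fold counts as a misclassification
#' (with a warning).
#'
#' @param fm A `feature_matrix` (or plain matrix together with `y`).
#' @param algorithm Algorithm name (see [default_param_grid()]).
#' @param params Named list of hyper-parameters for that algorithm.
#' @param y Labels when `fm` is a plain matrix.
#' @param response Label field when `fm` is a `feature_matrix`.
#' @return Accuracy as a percentage in `[0, 100]`.
#' @export
loocv_accuracy <- function(fm, algorithm, params, y = NULL, response = "type") {
  if (inherits(fm, "feature_matrix")) { y <- fm[[response]]; X <- fm$X } else X <- as.matrix(fm)
  n <- nrow(X)
  if (n < 2L) rc_error("invalid_parameter", "need at least two samples for LOOCV")
  correct <- 0L
  for (i in seq_len(n)) {
    pred <- tryCatch(
      fit_predict_labels(algorithm, X[-i, , drop = FALSE], y[-i],
                         X[i, , drop = FALSE], params),
      error = function(e) {
        warning(sprintf("fold %d failed (%s); counted as misclassification",
                        i, conditionMessage(e)))
        NA_character_
      })
    if (!is.na(pred) && pred == y[i]) correct <- correct + 1L
  }
  100 * correct / n
}

# Multi-LV LOOCV helpers: fit once per fold at the largest LV count and
# read off predictions for every smaller count. Returns accuracy (%) per lv.
loocv_multi_lv <- function(X, y, lvs, fitter, predictor) {
  n <- nrow(X)
  lvs <- sort(unique(lvs))
  correct <- numeric(length(lvs))
  for (i in seq_len(n)) {
    fit <- tryCatch(suppressWarnings(fitter(X[-i, , drop = FALSE], y[-i], max(lvs))),
                    error = function(e) NULL)
    for (li in seq_along(lvs)) {
      pred <- if (is.null(fit)) NA_character_ else
        tryCatch(predictor(fit, X[i, , drop = FALSE], lvs[li]),
                 error = function(e) NA_character_)
      if (!is.na(pred) && pred == y[i]) correct[li] <- correct[li] + 1L
    }
  }
  100 * correct / n
}

#' Exhaustive LOOCV grid search
#'
#' Evaluates [loocv_accuracy()] on the Cartesian product of the grid values
#' (sharing work across latent-variable counts for the PLS family) and
#' returns the best cell together with the full accuracy surface. Ties are
#' broken toward parsimony: fewest latent variables first, then the
#' smallest value of the remaining parameter (`k`, `C`, `sigma` or `phi`).
#' Grid values that are infeasible for the data size (`k > n - 1`,
#' `n_lv > min(n - 2, p)`) are dropped with a warning.
#'
#' @param fm A `feature_matrix` (or matrix with `y`).
#' @param algorithm Algorithm name.
#' @param grid Named list of parameter vectors (default
#'   [default_param_grid()]).
#' @param y,response As in [loocv_accuracy()].
#' @return List with `best_params` (named list), `best_accuracy` (%), and
#'   `surface` (data frame of every grid cell and its LOOCV accuracy).
#' @export
grid_search <- function(fm, algorithm, grid = default_param_grid(algorithm),
                        y = NULL, response = "type") {
  if (inherits(fm, "feature_matrix")) { y <- fm[[response]]; X <- fm$X } else X <- as.matrix(fm)
  n <- nrow(X); p <- ncol(X)
  if (!length(grid)) rc_error("invalid_parameter", "empty grid")
  if (!is.null(grid$k) && any(grid$k > n - 1L)) {
    warning("dropping k values exceeding the LOOCV training size")
    grid$k <- grid$k[grid$k <= n - 1L]
  }
  if (!is.null(grid$n_lv)) {
    cap <- min(n - 2L, p)
    if (any(grid$n_lv > cap)) {
      warning("dropping n_lv values exceeding the data rank limit")
      grid$n_lv <- grid$n_lv[grid$n_lv <= cap]
    }
  }
  if (any(!lengths(grid))) rc_error("invalid_parameter", "grid has no feasible values")

  surface <- switch(algorithm,
    knn = {
      D <- as.matrix(stats::dist(X)); diag(D) <- Inf
      classes <- sort(unique(y))
      ord <- apply(D, 1L, order) # n x n, column i = neighbours of i
      acc <- vapply(grid$k, function(k) {
        pred <- vapply(seq_len(n), function(i) {
          nb <- y[ord[seq_len(k), i]]
          cnt <- vapply(classes, function(cl) sum(nb == cl), numeric(1))
          classes[which.max(cnt)]
        }, character(1))
        100 * mean(pred == y)
      }, numeric(1))
      data.frame(k = grid$k, accuracy = acc)
    },
    plsda = {
      acc <- loocv_multi_lv(X, y, grid$n_lv,
        fitter = function(Xt, yt, a) pls_fit(Xt, yt, n_lv = a),
        predictor = function(fit, q, a) pls_predict(fit, q, n_lv = a)$labels)
      data.frame(n_lv = sort(unique(grid$n_lv)), accuracy = acc)
    },
    kplsda = {
      do.call(rbind, lapply(grid$sigma, function(s) {
        acc <- loocv_multi_lv(X, y, grid$n_lv,
          fitter = function(Xt, yt, a) kpls_fit(Xt, yt, n_lv = a, sigma = s),
          predictor = function(fit, q, a) kpls_predict(fit, q, n_lv = a)$labels)
        data.frame(n_lv = sort(unique(grid$n_lv)), sigma = s, accuracy = acc)
      }))
    },
    lwplsc = {
      lvs <- sort(unique(grid$n_lv))
      do.call(rbind, lapply(grid$phi, function(ph) {
        correct <- numeric(length(lvs))
        for (i in seq_len(n)) {
          sc <- lwplsc_scores_multi(X[-i, , drop = FALSE], y[-i],
                                    X[i, , drop = FALSE], ph, lvs)
          for (li in seq_along(lvs)) {
            lab <- decode_scores(matrix(sc[1L, , li], nrow = 1L), dimnames(sc)[[2]])
            if (lab == y[i]) correct[li] <- correct[li] + 1L
          }
        }
        data.frame(n_lv = lvs, phi = ph, accuracy = 100 * correct / n)
      }))
    },
    svm = {
      acc <- vapply(grid$C, function(Cv)
        loocv_accuracy(X, "svm", list(C = Cv, kernel = grid$kernel %||% "puk",
                                      puk_omega = grid$puk_omega %||% 1,
                                      puk_sigma = grid$puk_sigma %||% 1),
                       y = y), numeric(1))
      data.frame(C = grid$C, accuracy = acc)
    },
    rc_error("invalid_parameter", paste("unknown algorithm:", algorithm)))

  rownames(surface) <- NULL
  tie_cols <- intersect(c("n_lv", "k", "C", "sigma", "phi"), names(surface))
  ord <- do.call(order, c(list(-surface$accuracy), surface[tie_cols]))
  best <- surface[ord[1L], , drop = FALSE]
  best_params <- as.list(best[setdiff(names(best), "accuracy")])
  if (algorithm == "svm") # carry fixed kernel settings along with the best C
    best_params <- c(best_params,
                     list(kernel = grid$kernel %||% "puk",
                          puk_omega = grid$puk_omega %||% 1,
                          puk_sigma = grid$puk_sigma %||% 1))
  list(best_params = best_params, best_accuracy = best$accuracy,
       surface = surface)
}

#' Overall and per-class accuracy of predictions
#'
#' @param truth True labels.
#' @param pred Predicted labels (must come from the training label set).
#' @param classes Optional class order for the confusion matrix.
#' @return List of class `evaluation_report`: `overall` (%), `per_class`
#'   (named %, diagonal over row sums), `confusion` (rows = truth),
#'   `n` (sample count).
#' @export
evaluate_predictions <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred))
    rc_error("invalid_input", "truth and predictions differ in length")
  if (is.null(classes)) classes <- sort(unique(truth))
  if (!all(pred %in% classes))
    rc_error("reporting_error", "predicted labels outside the known class set")
  cm <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("truth", "predicted")
  per_class <- 100 * diag(cm) / rowSums(cm)
  structure(list(overall = 100 * mean(truth == pred),
                 per_class = per_class, confusion = cm, n = length(truth)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("overall accuracy: %.1f%% (n = %d)\n", x$overall, x$n))
  for (cl in names(x$per_class))
    cat(sprintf("  %-12s %.1f%%\n", cl, x$per_class[cl]))
  invisible(x)
}
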
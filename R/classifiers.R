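# The five classifiers: k-NN, SVM (SMO with the Pearson VII universal
# kernel), PLS-DA, Gaussian-kernel PLS-DA and the locally weighted PLS
# classifier. All are deterministic. PLS-family models share one (optionally
# sample-weighted) NIPALS core; class decisions are argmax over dummy-coded
# responses with ties broken toward the first class in sorted order.

#' Dummy (one-hot) coding of class labels
#'
#' @param labels Vector of class labels with at least two distinct values.
#' @return List with `Y` (`n x C` 0/1 indicator matrix, columns in sorted
#'   class order) and `class_order`.
#' @export
dummy_code <- function(labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    rc_error("degenerate_input", "need at least two classes for dummy coding")
  Y <- outer(labels, classes, `==`) * 1
  colnames(Y) <- classes
  list(Y = Y, class_order = classes)
}

# argmax decoding; ties go to the first (sorted-order) class
decode_scores <- function(scores, class_order) {
  class_order[max.col(scores, ties.method = "first")]
}

#' k-nearest-neighbour classification
#'
#' Majority vote over the `k` nearest training samples in Euclidean
#' distance; `k = 1` assigns the nearest neighbour's class. Vote ties are
#' broken toward the first class in sorted order; distance ties toward the
#' lower sample index.
#'
#' @param X `n x p` training matrix (or `feature_matrix`).
#' @param y Length-`n` training labels (ignored if `X` is a
#'   `feature_matrix`; see `response`).
#' @param query `m x p` matrix (or vector) of queries.
#' @param k Number of neighbours, `<= n`.
#' @param response Label field used when `X` is a `feature_matrix`
#'   (`"type"` or `"species"`).
#' @return Character vector of `m` predicted labels.
#' @export
knn_predict <- function(X, y = NULL, query, k = 1L, response = "type") {
  if (inherits(X, "feature_matrix")) { y <- X[[response]]; X <- X$X }
  X <- as.matrix(X)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (k < 1L || k > nrow(X))
    rc_error("invalid_parameter", "k must lie in [1, n_train]")
  y <- as.character(y)
  classes <- sort(unique(y))
  d2 <- outer(rowSums(query^2), rep(1, nrow(X))) +
    outer(rep(1, nrow(query)), rowSums(X^2)) - 2 * tcrossprod(query, X)
  apply(d2, 1L, function(dr) {
    nb <- y[order(dr)[seq_len(k)]]
    cnt <- vapply(classes, function(cl) sum(nb == cl), numeric(1))
    classes[which.max(cnt)]
  })
}

## ---------------------------------------------------------------------------
## PLS-DA (optionally sample-weighted NIPALS)

# Weighted NIPALS. X (n x p), Y (n x C), weights (n, >= 0, sum > 0).
# Returns loadings/weights per component plus weighted means. With uniform
# weights this is the standard NIPALS with X- and Y-deflation.
nipals_pls <- function(X, Y, n_lv, weights = NULL, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); C <- ncol(Y)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- weights / sum(weights)
  x_mean <- as.numeric(crossprod(sw, X))
  y_mean <- as.numeric(crossprod(sw, Y))
  Xc <- sweep(X, 2L, x_mean)
  Yc <- sweep(Y, 2L, y_mean)
  a_max <- min(n_lv, n - 1L, p)
  W <- matrix(0, p, a_max); P <- matrix(0, p, a_max)
  Q <- matrix(0, C, a_max); Tsc <- matrix(0, n, a_max)
  x_ss0 <- sum(weights * Xc^2)
  a_used <- 0L
  for (a in seq_len(a_max)) {
    if (sum(weights * Xc^2) < max(x_ss0, 1) * 1e-14) break
    u <- Yc[, which.max(colSums(weights * Yc^2))]
    if (sum(u^2) < 1e-30) u <- Yc[, 1L]
    t_ <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xc, weights * u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-30) break
      w <- w / nw
      t_new <- Xc %*% w
      q <- crossprod(Yc, weights * t_new) / sum(weights * t_new^2)
      u_new <- Yc %*% q / sum(q^2)
      if (!is.null(t_) && sum((t_new - t_)^2) <= tol * sum(t_new^2)) { t_ <- t_new; break }
      t_ <- t_new
      u <- u_new
    }
    if (is.null(t_) || sum(weights * t_^2) < 1e-30) break
    denom <- sum(weights * t_^2)
    p_ <- crossprod(Xc, weights * t_) / denom
    q <- crossprod(Yc, weights * t_) / denom
    Xc <- Xc - t_ %*% t(p_)
    Yc <- Yc - t_ %*% t(q)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q; Tsc[, a] <- t_
    a_used <- a
  }
  if (a_used < n_lv)
    warning(sprintf("latent variables reduced from %d to %d (rank limit)", n_lv, a_used))
  idx <- seq_len(max(a_used, 1L))
  list(x_mean = x_mean, y_mean = y_mean,
       W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       Q = Q[, idx, drop = FALSE], scores = Tsc[, idx, drop = FALSE],
       n_lv = a_used)
}

#' Fit a PLS-DA model
#'
#' Dummy-codes the labels, mean-centres `X` and `Y` on the training data and
#' extracts latent variables by NIPALS, deflating both `X` and `Y` by their
#' rank-one score approximations. If `n_lv` exceeds the data rank it is
#' reduced with a warning.
#'
#' @param X `n x p` training matrix (or `feature_matrix`).
#' @param y Training labels (or `NULL` to use `response` of a
#'   `feature_matrix`).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @param weights Optional positive sample weights (used by the locally
#'   weighted classifier).
#' @param response Label field when `X` is a `feature_matrix`.
#' @return Object of class `pls_model`.
#' @export
pls_fit <- function(X, y = NULL, n_lv = 2L, weights = NULL, response = "type") {
  if (inherits(X, "feature_matrix")) { y <- X[[response]]; X <- X$X }
  X <- as.matrix(X)
  if (n_lv < 1L) rc_error("invalid_parameter", "n_lv must be >= 1")
  dc <- dummy_code(y)
  fit <- nipals_pls(X, dc$Y, n_lv, weights = weights)
  structure(c(fit, list(class_order = dc$class_order)), class = "pls_model")
}

# Regression coefficients truncated to a components.
pls_coef <- function(model, a = model$n_lv) {
  a <- min(a, model$n_lv)
  W <- model$W[, seq_len(a), drop = FALSE]
  P <- model$P[, seq_len(a), drop = FALSE]
  Q <- model$Q[, seq_len(a), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Predict from a PLS-DA model
#'
#' Continuous class scores are `(Xnew - x_mean) B + y_mean`; the label is
#' the argmax across class columns.
#'
#' @param model A `pls_model`.
#' @param X `m x p` matrix (or vector, or `feature_matrix`).
#' @param n_lv Use only the first `n_lv` latent variables (default: all
#'   fitted).
#' @return List with `scores` (`m x C`) and `labels` (length `m`).
#' @export
pls_predict <- function(model, X, n_lv = model$n_lv) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$x_mean))
    rc_error("invalid_input", "query dimension does not match training data")
  B <- pls_coef(model, n_lv)
  scores <- sweep(as.matrix(X), 2L, model$x_mean) %*% B
  scores <- sweep(scores, 2L, model$y_mean, `+`)
  colnames(scores) <- model$class_order
  list(scores = scores, labels = decode_scores(scores, model$class_order))
}

## ---------------------------------------------------------------------------
## Kernel PLS-DA

#' Gaussian (RBF) kernel Gram matrix
#'
#' `K[i, j] = exp(-||a_i - b_j||^2 / (2 sigma^2))`.
#'
#' @param A `n x p` matrix.
#' @param B `m x p` matrix (default `A`).
#' @param sigma Positive kernel width.
#' @return `n x m` Gram matrix.
#' @export
gaussian_kernel <- function(A, B = A, sigma) {
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    rc_error("invalid_parameter", "sigma must be > 0")
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

kernel_gram <- function(A, B, kernel, sigma) {
  switch(kernel,
         gaussian = gaussian_kernel(A, B, sigma),
         linear = tcrossprod(as.matrix(A), as.matrix(B)),
         rc_error("invalid_parameter", paste("unknown kernel:", kernel)))
}

#' Fit a kernel PLS-DA model
#'
#' Builds the training Gram matrix, double-centres it and extracts latent
#' variables with kernel NIPALS in dual form; with a linear kernel this
#' reproduces ordinary PLS-DA scores.
#'
#' @param X `n x p` training matrix (or `feature_matrix`).
#' @param y Training labels.
#' @param n_lv Number of latent variables.
#' @param sigma Gaussian kernel width (ignored for the linear kernel).
#' @param kernel `"gaussian"` (default) or `"linear"`.
#' @param response Label field when `X` is a `feature_matrix`.
#' @return Object of class `kpls_model` retaining the training inputs.
#' @export
kpls_fit <- function(X, y = NULL, n_lv = 2L, sigma = 1, kernel = "gaussian",
                     response = "type") {
  if (inherits(X, "feature_matrix")) { y <- X[[response]]; X <- X$X }
  X <- as.matrix(X)
  if (n_lv < 1L) rc_error("invalid_parameter", "n_lv must be >= 1")
  dc <- dummy_code(y)
  K <- kernel_gram(X, X, kernel, sigma)
  fit <- kernel_nipals(K, dc$Y, n_lv)
  structure(c(fit, list(X_train = X, kernel = kernel, sigma = sigma,
                        k_colmeans = colMeans(K),
                        class_order = dc$class_order)),
            class = "kpls_model")
}

# Kernel NIPALS on an uncentered Gram K and dummy Y (Rosipal & Trejo dual
# form). Stores normalized score vectors T and Y-space vectors U needed for
# the dual regression coefficients.
kernel_nipals <- function(K, Y, n_lv, tol = 1e-10, max_iter = 500L) {
  n <- nrow(K)
  Cn <- diag(n) - matrix(1 / n, n, n)
  Kc <- Cn %*% K %*% Cn
  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_mean)
  Kd <- Kc; Yd <- Yc
  a_max <- min(n_lv, n - 1L)
  Tm <- matrix(0, n, a_max); Um <- matrix(0, n, a_max)
  a_used <- 0L
  for (a in seq_len(a_max)) {
    if (sum(diag(Kd)) < 1e-12 * max(1, sum(diag(Kc)))) break
    u <- Yd[, which.max(colSums(Yd^2))]
    if (sum(u^2) < 1e-30) break
    t_ <- NULL
    for (it in seq_len(max_iter)) {
      t_new <- Kd %*% u
      nt <- sqrt(sum(t_new^2))
      if (nt < 1e-30) { t_new <- NULL; break }
      t_new <- t_new / nt
      cvec <- crossprod(Yd, t_new)
      u_new <- Yd %*% cvec
      u_new <- u_new / sqrt(sum(u_new^2))
      if (!is.null(t_) && sum((t_new - t_)^2) <= tol) { t_ <- t_new; u <- u_new; break }
      t_ <- t_new; u <- u_new
    }
    if (is.null(t_)) break
    Pr <- diag(n) - tcrossprod(t_)
    Kd <- Pr %*% Kd %*% Pr
    Yd <- Yd - t_ %*% crossprod(t_, Yd)
    Tm[, a] <- t_; Um[, a] <- u
    a_used <- a
  }
  if (a_used < n_lv)
    warning(sprintf("latent variables reduced from %d to %d (rank limit)", n_lv, a_used))
  idx <- seq_len(max(a_used, 1L))
  list(scores = Tm[, idx, drop = FALSE], U = Um[, idx, drop = FALSE],
       Kc = Kc, Yc = Yc, y_mean = y_mean, n_lv = a_used)
}

#' Predict from a kernel PLS-DA model
#'
#' Computes the query-versus-training Gram matrix, centres it consistently
#' with the training double-centring and applies the dual regression
#' coefficients; the label is the argmax across class columns.
#'
#' @param model A `kpls_model`.
#' @param X `m x p` matrix (or vector, or `feature_matrix`).
#' @param n_lv Use only the first `n_lv` latent variables.
#' @return List with `scores` and `labels`.
#' @export
kpls_predict <- function(model, X, n_lv = model$n_lv) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != ncol(model$X_train))
    rc_error("invalid_input", "query dimension does not match training data")
  a <- min(n_lv, model$n_lv)
  Tm <- model$scores[, seq_len(a), drop = FALSE]
  Um <- model$U[, seq_len(a), drop = FALSE]
  B <- Um %*% solve(crossprod(Tm, model$Kc %*% Um), crossprod(Tm, model$Yc))
  Kt <- kernel_gram(X, model$X_train, model$kernel, model$sigma)
  M <- sweep(Kt, 2L, model$k_colmeans)   # subtract training column means
  M <- M - rowMeans(M)                   # right-centring
  scores <- M %*% B
  scores <- sweep(scores, 2L, model$y_mean, `+`)
  colnames(scores) <- model$class_order
  list(scores = scores, labels = decode_scores(scores, model$class_order))
}

## ---------------------------------------------------------------------------
## Locally weighted PLS classifier (just-in-time)

#' Locally weighted PLS classification of queries
#'
#' Just-in-time modelling: for each query, training samples are weighted by
#' similarity `w_n = exp(-d_n / (phi * s_d))`, where `d_n` is the Euclidean
#' distance from the query to sample `n` and `s_d` the standard deviation
#' of those distances; a sample-weighted PLS-DA model is then fitted and
#' the query predicted. Small `phi` localizes the model around the query;
#' as `phi` grows the weights become uniform and the prediction converges
#' to global PLS-DA.
#'
#' @param X `n x p` training matrix (or `feature_matrix`).
#' @param y Training labels.
#' @param query `m x p` matrix (or vector) of queries.
#' @param phi Positive localization parameter.
#' @param n_lv Latent variables of each local model.
#' @param response Label field when `X` is a `feature_matrix`.
#' @return List with `scores` (`m x C`) and `labels`.
#' @export
lwplsc_predict <- function(X, y = NULL, query, phi = 1, n_lv = 2L,
                           response = "type") {
  res <- lwplsc_scores_multi(X, y, query, phi, n_lv, response)
  scores <- res[, , 1L, drop = FALSE]
  dim(scores) <- dim(res)[1:2]
  colnames(scores) <- dimnames(res)[[2]]
  list(scores = scores, labels = decode_scores(scores, dimnames(res)[[2]]))
}

# Multi-LV workhorse: returns an m x C x length(lvs) array of continuous
# scores, fitting each local model once at max(lvs). Used by the grid
# search so one LOOCV pass covers every candidate LV count.
lwplsc_scores_multi <- function(X, y = NULL, query, phi, lvs, response = "type") {
  if (inherits(X, "feature_matrix")) { y <- X[[response]]; X <- X$X }
  X <- as.matrix(X)
  if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
  if (length(phi) != 1L || is.na(phi) || phi <= 0)
    rc_error("invalid_parameter", "phi must be > 0")
  lvs <- sort(unique(as.integer(lvs)))
  dc <- dummy_code(y)
  m <- nrow(query); C <- length(dc$class_order)
  out <- array(NA_real_, dim = c(m, C, length(lvs)),
               dimnames = list(NULL, dc$class_order, paste0("lv", lvs)))
  for (qi in seq_len(m)) {
    q <- query[qi, ]
    d <- sqrt(rowSums(sweep(X, 2L, q)^2))
    s_d <- stats::sd(d)
    w <- if (is.na(s_d) || s_d == 0) rep(1, nrow(X)) else exp(-d / (phi * s_d))
    if (max(w) < 1e-300) {
      warning("all similarity weights underflowed; falling back to global PLS-DA")
      w <- rep(1, nrow(X))
    }
    fit <- suppressWarnings(nipals_pls(X, dc$Y, max(lvs), weights = w))
    xc <- q - fit$x_mean
    for (li in seq_along(lvs)) {
      a <- min(lvs[li], fit$n_lv)
      B <- fit$W[, seq_len(a), drop = FALSE] %*%
        solve(crossprod(fit$P[, seq_len(a), drop = FALSE],
                        fit$W[, seq_len(a), drop = FALSE]),
              t(fit$Q[, seq_len(a), drop = FALSE]))
      out[qi, , li] <- as.numeric(xc %*% B) + fit$y_mean
    }
  }
  out
}

## ---------------------------------------------------------------------------
## SVM with the Pearson VII universal kernel

#' Pearson VII universal kernel (PUK) Gram matrix
#'
#' `k(x, y) = 1 / (1 + (2 sqrt(2^(1/omega) - 1) ||x - y|| / sigma)^2)^omega`,
#' with unit value at zero distance.
#'
#' @param A `n x p` matrix.
#' @param B `m x p` matrix (default `A`).
#' @param omega Tailing (shape) parameter, > 0.
#' @param sigma Width parameter, > 0.
#' @return `n x m` Gram matrix with entries in `(0, 1]`.
#' @export
puk_kernel <- function(A, B = A, omega = 1, sigma = 1) {
  if (omega <= 0 || sigma <= 0)
    rc_error("invalid_parameter", "PUK parameters must be > 0")
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d <- sqrt(pmax(d2, 0))
  1 / (1 + (2 * sqrt(2^(1 / omega) - 1) * d / sigma)^2)^omega
}

svm_gram <- function(A, B, cfg) {
  switch(cfg$kernel,
         puk = puk_kernel(A, B, cfg$puk_omega, cfg$puk_sigma),
         gaussian = gaussian_kernel(A, B, cfg$sigma),
         linear = tcrossprod(as.matrix(A), as.matrix(B)),
         rc_error("invalid_parameter", paste("unknown kernel:", cfg$kernel)))
}

#' Fit a binary soft-margin kernel SVM
#'
#' Deterministic sequential minimal optimization (SMO) of the dual problem.
#' The default kernel is PUK with `omega = 1`, `sigma = 1`; the positive
#' class is the second label in sorted class order.
#'
#' @param X `n x p` training matrix (or `feature_matrix`).
#' @param y Binary training labels.
#' @param C Penalty parameter, > 0.
#' @param kernel `"puk"`, `"gaussian"` or `"linear"`.
#' @param puk_omega,puk_sigma PUK parameters.
#' @param sigma Gaussian kernel width.
#' @param tol KKT violation tolerance.
#' @param max_sweeps Cap on full passes over the training set.
#' @param response Label field when `X` is a `feature_matrix`.
#' @return Object of class `svm_model` (`alpha`, `b`, support-vector data,
#'   kernel settings, class order).
#' @export
svm_fit <- function(X, y = NULL, C = 1, kernel = "puk", puk_omega = 1,
                    puk_sigma = 1, sigma = 1, tol = 1e-3, max_sweeps = 200L,
                    response = "type") {
  if (inherits(X, "feature_matrix")) { y <- X[[response]]; X <- X$X }
  X <- as.matrix(X)
  if (C <= 0) rc_error("invalid_parameter", "C must be > 0")
  classes <- sort(unique(as.character(y)))
  if (length(classes) != 2L)
    rc_error("unsupported_configuration", "SVM supports exactly two classes")
  yv <- ifelse(as.character(y) == classes[2L], 1, -1)
  cfg <- list(kernel = kernel, puk_omega = puk_omega, puk_sigma = puk_sigma,
              sigma = sigma)
  K <- svm_gram(X, X, cfg)
  n <- nrow(X)
  alpha <- numeric(n); b <- 0
  f <- numeric(n) # decision values K %*% (alpha*y) + b
  for (sweep_i in seq_len(max_sweeps)) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- f[i] - yv[i]
      if (!((yv[i] * Ei < -tol && alpha[i] < C) || (yv[i] * Ei > tol && alpha[i] > 0)))
        next
      E <- f - yv
      # partners in decreasing |Ei - Ej|; fall through degenerate pairs
      for (j in order(-abs(Ei - E))) {
        if (j == i) next
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (yv[i] != yv[j]) {
          L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - yv[j] * (Ei - E[j]) / eta
        aj <- min(max(aj, L), H)
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + yv[i] * yv[j] * (aj_old - aj)
        b1 <- b - Ei - yv[i] * (ai - ai_old) * K[i, i] - yv[j] * (aj - aj_old) * K[i, j]
        b2 <- b - E[j] - yv[i] * (ai - ai_old) * K[i, j] - yv[j] * (aj - aj_old) * K[j, j]
        b_new <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        f <- f + yv[i] * (ai - ai_old) * K[, i] + yv[j] * (aj - aj_old) * K[, j] +
          (b_new - b)
        alpha[i] <- ai; alpha[j] <- aj; b <- b_new
        changed <- changed + 1L
        break
      }
    }
    if (changed == 0L) break
  }
  structure(list(alpha = alpha, b = b, X_train = X, y_sign = yv, C = C,
                 cfg = cfg, class_order = classes),
            class = "svm_model")
}

#' Predict from a fitted SVM
#'
#' @param model An `svm_model`.
#' @param X `m x p` matrix (or vector, or `feature_matrix`).
#' @return List with `decision` (signed decision values) and `labels`.
#' @export
svm_predict <- function(model, X) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  Kt <- svm_gram(X, model$X_train, model$cfg)
  dec <- as.numeric(Kt %*% (model$alpha * model$y_sign) + model$b)
  labels <- ifelse(dec > 0, model$class_order[2L], model$class_order[1L])
  list(decision = dec, labels = labels)
}

## ---------------------------------------------------------------------------
## JSON model persistence

#' Save a PLS-family or SVM model to JSON
#'
#' Serializes coefficients, centring vectors, kernel settings and class
#' order at full precision so that [load_model()] reproduces predictions.
#'
#' @param model A `pls_model`, `kpls_model` or `svm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  kind <- class(model)[1L]
  payload <- lapply(unclass(model), function(x) {
    if (is.matrix(x)) list(.matrix = TRUE, dim = dim(x), data = as.numeric(x)) else x
  })
  jsonlite::write_json(list(kind = kind, fields = payload), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path JSON path.
#' @return The restored model object.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields <- lapply(obj$fields, function(x) {
    if (is.list(x) && isTRUE(x$.matrix)) matrix(x$data, x$dim[1], x$dim[2]) else x
  })
  # restore nested svm kernel config as a plain list
  if (obj$kind == "svm_model" && is.data.frame(fields$cfg))
    fields$cfg <- as.list(fields$cfg)
  structure(fields, class = obj$kind)
}
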
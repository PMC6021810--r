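# Classifier unit tests: oracle equivalences, limiting cases, invariants.

test_that("dummy_code builds sorted one-hot rows and round-trips", {
  dc <- dummy_code(c("a", "b", "a"))
  expect_equal(unname(dc$Y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(dc$class_order, c("a", "b"))
  dc3 <- dummy_code(c("z", "m", "a", "m"))
  expect_equal(ncol(dc3$Y), 3)
  expect_true(all(rowSums(dc3$Y) == 1))
  # decode(code(labels)) = labels
  lab <- c("x", "y", "x", "z", "y")
  dc4 <- dummy_code(lab)
  expect_equal(rainbowclass:::decode_scores(dc4$Y, dc4$class_order), lab)
  expect_error(dummy_code(rep("only", 4)), class = "degenerate_input")
})

test_that("knn_predict matches definitions and the brute-force oracle", {
  tb <- toy_binary()
  expect_equal(knn_predict(tb$X, tb$y, tb$X[3, ], k = 1), tb$y[3])
  X <- rbind(c(1, 0), c(2, 0)); y <- c("near", "far")
  expect_equal(knn_predict(X, y, c(0, 0), k = 1), "near")
  set.seed(41)
  Xr <- matrix(rnorm(20 * 4), 20, 4)
  yr <- sample(c("a", "b"), 20, replace = TRUE)
  Q <- matrix(rnorm(6 * 4), 6, 4)
  oracle <- apply(Q, 1, function(q) {
    d <- sqrt(colSums((t(Xr) - q)^2))
    nb <- yr[order(d)[1:5]]
    names(sort(table(factor(nb, levels = sort(unique(yr)))), decreasing = TRUE))[1]
  })
  # oracle tie-break: table order is sorted class order; sort is stable
  expect_equal(knn_predict(Xr, yr, Q, k = 5), unname(oracle))
  expect_error(knn_predict(Xr, yr, Q, k = 21), class = "invalid_parameter")
})

test_that("PUK kernel is unit at zero distance and SVM separates separable data", {
  x <- matrix(rnorm(10), 2, 5)
  expect_equal(diag(puk_kernel(x, x)), c(1, 1))
  tb <- toy_binary(n = 30, p = 2, seed = 43, sep = 3)
  m <- svm_fit(tb$X, tb$y, C = 100, kernel = "linear")
  expect_equal(svm_predict(m, tb$X)$labels, tb$y)
})

test_that("SMO solution matches an exhaustive dual-QP oracle on a 4-point set", {
  X <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- c("a", "a", "b", "b")
  Cpen <- 1
  m <- svm_fit(X, y, C = Cpen, kernel = "linear")
  K <- tcrossprod(X)
  ys <- ifelse(y == "b", 1, -1)
  dual_obj <- function(a) sum(a) - 0.5 * sum((a * ys) %o% (a * ys) * K)
  # exhaustive grid over the box, filtered to the equality constraint
  g <- seq(0, Cpen, by = 0.05)
  grid <- as.matrix(expand.grid(g, g, g, g))
  ok <- abs(grid %*% ys) < 1e-9
  vals <- apply(grid[ok, ], 1, dual_obj)
  best <- grid[ok, ][which.max(vals), ]
  expect_equal(dual_obj(m$alpha), max(vals), tolerance = 1e-3)
  expect_equal(which(m$alpha > 1e-6), unname(which(best > 1e-6)))
  expect_equal(svm_predict(m, X)$labels, y)
})

test_that("PLS recovers an exact single-factor response and equals OLS at full rank", {
  set.seed(44)
  # orthonormal AND mean-centred columns (QR of a centred matrix stays in
  # its centred column space) make y = X[,1] exactly rank-one recoverable
  X <- qr.Q(qr(scale(matrix(rnorm(20 * 5), 20, 5), scale = FALSE)))
  Y <- X[, 1, drop = FALSE]
  fit <- rainbowclass:::nipals_pls(X, Y, 1)
  pred <- sweep(X, 2, fit$x_mean) %*% (fit$W %*% solve(crossprod(fit$P, fit$W), t(fit$Q))) +
    fit$y_mean
  expect_lt(max(abs(pred - Y)), 1e-8)
  # full-rank PLS = OLS on centered data
  tb <- toy_binary(n = 16, p = 6, seed = 45, sep = 0.5)
  m <- suppressWarnings(pls_fit(tb$X, tb$y, n_lv = 6))
  pr <- pls_predict(m, tb$X)
  dc <- dummy_code(tb$y)
  Xc <- scale(tb$X, scale = FALSE); Yc <- scale(dc$Y, scale = FALSE)
  ols <- sweep(Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc)), 2,
               colMeans(dc$Y), `+`)
  expect_lt(max(abs(pr$scores - ols)), 1e-6)
  expect_equal(pls_predict(m, tb$X)$labels, pr$labels) # deterministic
})

test_that("PLS scores are orthogonal and training RSS is monotone in LVs", {
  tb <- toy_binary(n = 24, p = 10, seed = 46, sep = 0.3)
  m <- pls_fit(tb$X, tb$y, n_lv = 6)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  dc <- dummy_code(tb$y)
  rss <- vapply(1:6, function(a)
    sum((pls_predict(m, tb$X, n_lv = a)$scores - dc$Y)^2), numeric(1))
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("pls_predict centering identity and column-permutation invariance", {
  tb <- toy_binary(n = 20, p = 6, seed = 47)
  m <- pls_fit(tb$X, tb$y, n_lv = 3)
  pr <- pls_predict(m, m$x_mean)
  expect_equal(as.numeric(pr$scores), unname(m$y_mean), tolerance = 1e-12)
  perm <- c(4, 1, 6, 2, 5, 3)
  m2 <- pls_fit(tb$X[, perm], tb$y, n_lv = 3)
  q <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(pls_predict(m2, q[, perm])$labels, pls_predict(m, q)$labels)
  expect_error(pls_predict(m, matrix(0, 2, 4)), class = "invalid_input")
})

test_that("gaussian_kernel matches its formula and invariances", {
  expect_equal(gaussian_kernel(matrix(c(0, 0), 1), matrix(c(3, 4), 1), sigma = 5)[1, 1],
               exp(-0.5))
  set.seed(48); A <- matrix(rnorm(12), 4, 3)
  K <- gaussian_kernel(A, A, sigma = 2)
  expect_equal(diag(K), rep(1, 4))
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_lt(max(abs(gaussian_kernel(A, A, sigma = 1e8) - 1)), 1e-9)
  # doubling sigma and rescaling inputs by 2 leaves the Gram unchanged
  expect_equal(gaussian_kernel(2 * A, 2 * A, sigma = 2), gaussian_kernel(A, A, sigma = 1))
  expect_error(gaussian_kernel(A, A, sigma = 0), class = "invalid_parameter")
})

test_that("kernel PLS with a linear kernel reproduces PLS-DA", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:30, 1); p <- sample(4:10, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c("a", "b"), length.out = n)
    Xt <- matrix(rnorm(6 * p), 6, p)
    a <- min(4, n - 2)
    mk <- suppressWarnings(kpls_fit(X, y, n_lv = a, kernel = "linear"))
    mp <- suppressWarnings(pls_fit(X, y, n_lv = a))
    expect_lt(max(abs(kpls_predict(mk, Xt)$scores - pls_predict(mp, Xt)$scores)),
              1e-6)
  }
})

test_that("kernel PLS interpolates training data in the high-LV regime", {
  set.seed(49)
  X <- matrix(rnorm(12 * 3), 12, 3)
  y <- rep(c("a", "b"), 6)
  m <- suppressWarnings(kpls_fit(X, y, n_lv = 11, sigma = 2))
  expect_equal(kpls_predict(m, X)$labels, y)
})

test_that("locally weighted PLS has the correct limits", {
  tb <- toy_binary(n = 20, p = 5, seed = 50, sep = 1)
  q <- matrix(rnorm(3 * 5), 3, 5)
  glob <- pls_predict(pls_fit(tb$X, tb$y, n_lv = 2), q)
  lw <- lwplsc_predict(tb$X, tb$y, q, phi = 1e12, n_lv = 2)
  expect_lt(max(abs(lw$scores - glob$scores)), 1e-6)
  # tiny phi: a query sitting on a training point inherits its class
  for (i in c(1, 11)) {
    pr <- lwplsc_predict(tb$X, tb$y, tb$X[i, ], phi = 0.05, n_lv = 1)
    expect_equal(pr$labels, tb$y[i])
  }
  expect_error(lwplsc_predict(tb$X, tb$y, q, phi = 0), class = "invalid_parameter")
})

test_that("localization is monotone: smaller phi widens the weight contrast", {
  tb <- toy_binary(n = 16, p = 4, seed = 51)
  q <- rnorm(4)
  d <- sqrt(rowSums(sweep(tb$X, 2, q)^2))
  s <- sd(d)
  ratios <- vapply(c(25, 10, 5, 2, 1, 0.5, 0.1), function(phi) {
    w <- exp(-d / (phi * s))
    w[which.min(d)] / w[which.max(d)]
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("LW-PLSC beats global PLS-DA on a two-arc (moons) problem", {
  set.seed(52)
  n <- 30
  th1 <- seq(0, pi, length.out = n)
  th2 <- seq(pi, 2 * pi, length.out = n)
  X <- rbind(cbind(cos(th1), sin(th1)),
             cbind(1 + cos(th2), 0.5 + sin(th2))) +
    matrix(rnorm(4 * n, 0, 0.08), 2 * n, 2)
  y <- rep(c("a", "b"), each = n)
  pls_best <- suppressWarnings(
    grid_search(X, "plsda", list(n_lv = 1:2), y = y))$best_accuracy
  lw_best <- grid_search(X, "lwplsc",
                         list(n_lv = 2, phi = c(0.1, 0.5, 1, 2, 5)),
                         y = y)$best_accuracy
  expect_gt(lw_best, pls_best)
})

test_that("saved models reproduce predictions after reload", {
  pop <- small_population()
  fm <- pop$fm
  q <- fm$X[seq(1, 60, by = 7), ]
  mp <- pls_fit(fm, n_lv = 3)
  mk <- kpls_fit(fm, n_lv = 3, sigma = 100)
  for (m in list(mp, mk)) {
    f <- withr::local_tempfile(fileext = ".json")
    save_model(m, f)
    m2 <- load_model(f)
    pr1 <- if (inherits(m, "pls_model")) pls_predict(m, q) else kpls_predict(m, q)
    pr2 <- if (inherits(m, "pls_model")) pls_predict(m2, q) else kpls_predict(m2, q)
    expect_lt(max(abs(pr1$scores - pr2$scores)), 1e-12)
    expect_identical(pr1$labels, pr2$labels)
  }
  ms <- svm_fit(fm$X[1:30, ], fm$type[1:30], C = 2)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(ms, f)
  expect_equal(svm_predict(load_model(f), q)$decision, svm_predict(ms, q)$decision,
               tolerance = 1e-8)
})

test_that("all classifiers only emit training labels and are deterministic", {
  pop <- small_population()
  fm <- pop$fm
  tr <- fm_sub <- rainbowclass:::fm_subset(fm, 1:40)
  q <- fm$X[41:60, ]
  labs <- sort(unique(fm$type))
  preds <- list(
    knn_predict(tr, query = q, k = 3),
    svm_predict(svm_fit(tr, C = 2), q)$labels,
    pls_predict(pls_fit(tr, n_lv = 3), q)$labels,
    kpls_predict(kpls_fit(tr, n_lv = 3, sigma = 100), q)$labels,
    lwplsc_predict(tr, query = q, phi = 2, n_lv = 2)$labels)
  for (p in preds) expect_true(all(p %in% labs))
  expect_identical(preds[[5]], lwplsc_predict(tr, query = q, phi = 2, n_lv = 2)$labels)
})
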
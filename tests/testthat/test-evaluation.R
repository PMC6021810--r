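# DUPLEX splitting, LOOCV, grid search and accuracy reporting.

test_that("duplex_split honours the 2:1 quota and assigns the extreme pair to training", {
  set.seed(61)
  X <- matrix(runif(12), 6, 2)
  s <- duplex_split(X)
  expect_length(s$train_idx, 4)
  expect_length(s$test_idx, 2)
  expect_length(intersect(s$train_idx, s$test_idx), 0)
  expect_setequal(c(s$train_idx, s$test_idx), 1:6)
  D <- as.matrix(dist(X))
  far <- sort(which(D == max(D), arr.ind = TRUE)[1, ])
  expect_true(all(far %in% s$train_idx))
  # determinism
  expect_identical(duplex_split(X), s)
  expect_error(duplex_split(X[1:3, ]), class = "invalid_parameter")
})

test_that("duplex subsets preserve the spread of the data", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(runif(60), 30, 2)
    s <- duplex_split(X)
    spread <- function(idx) max(dist(X[idx, ]))
    r <- spread(s$train_idx) / spread(s$test_idx)
    expect_true(r >= 0.5 && r <= 2)
  }
})

test_that("loocv_accuracy matches explicit hold-one-out enumeration", {
  tb <- toy_binary(n = 20, p = 3, seed = 62, sep = 3)
  expect_equal(loocv_accuracy(tb$X, "knn", list(k = 1), y = tb$y), 100)
  # n = 4 toy: hand-rolled loop oracle
  X4 <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), 4, 2, byrow = TRUE)
  y4 <- c("a", "a", "b", "b")
  hand <- mean(vapply(1:4, function(i)
    knn_predict(X4[-i, ], y4[-i], X4[i, ], k = 1) == y4[i], logical(1))) * 100
  expect_equal(loocv_accuracy(X4, "knn", list(k = 1), y = y4), hand)
  hand_pls <- mean(vapply(1:4, function(i)
    pls_predict(pls_fit(X4[-i, ], y4[-i], n_lv = 1), X4[i, ])$labels == y4[i],
    logical(1))) * 100
  expect_equal(loocv_accuracy(X4, "plsda", list(n_lv = 1), y = y4), hand_pls)
})

test_that("label-independent features give chance-level LOOCV accuracy", {
  set.seed(63)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("a", "b"), 20)
  acc <- loocv_accuracy(X, "knn", list(k = 5), y = y)
  expect_true(acc > 25 && acc < 75)
})

test_that("grid_search finds the uniquely best parameter and is self-consistent", {
  # same-class pairs far apart: k = 1 is perfect, k = 3 votes across pairs
  centers <- seq(0, 30, by = 10)
  X <- cbind(rep(centers, each = 2) + rep(c(-0.1, 0.1), 4), 0)
  y <- rep(c("a", "b"), each = 2, times = 2)
  gs <- grid_search(X, "knn", list(k = c(1, 3)), y = y)
  expect_equal(gs$best_params$k, 1)
  expect_equal(gs$best_accuracy, 100)
  expect_equal(gs$best_accuracy, max(gs$surface$accuracy))
  # single-point grid returns that point
  gs1 <- grid_search(X, "knn", list(k = 3), y = y)
  expect_equal(gs1$best_params$k, 3)
  expect_equal(nrow(gs1$surface), 1)
})

test_that("grid_search ties break toward parsimony", {
  tb <- toy_binary(n = 20, p = 3, seed = 64, sep = 4) # trivially separable
  gs <- grid_search(tb$X, "knn", list(k = c(1, 3, 5)), y = tb$y)
  expect_equal(gs$surface$accuracy, rep(100, 3))
  expect_equal(gs$best_params$k, 1)
  gsl <- suppressWarnings(grid_search(tb$X, "plsda", list(n_lv = 1:3), y = tb$y))
  expect_equal(gsl$best_params$n_lv, min(gsl$surface$n_lv[
    gsl$surface$accuracy == max(gsl$surface$accuracy)]))
})

test_that("grid_search drops infeasible values and LOOCV is deterministic", {
  tb <- toy_binary(n = 12, p = 4, seed = 65)
  expect_warning(gs <- grid_search(tb$X, "knn", list(k = c(1, 3, 49)), y = tb$y),
                 "dropping k")
  expect_true(all(gs$surface$k <= 11))
  a1 <- loocv_accuracy(tb$X, "plsda", list(n_lv = 2), y = tb$y)
  a2 <- loocv_accuracy(tb$X, "plsda", list(n_lv = 2), y = tb$y)
  expect_identical(a1, a2)
})

test_that("evaluate_predictions computes overall and per-class accuracy", {
  ev <- evaluate_predictions(c("o", "o", "n", "n"), c("o", "n", "n", "n"))
  expect_equal(ev$overall, 75)
  expect_equal(unname(ev$per_class[c("o", "n")]), c(50, 100))
  expect_equal(sum(ev$confusion), 4)
  ev2 <- evaluate_predictions(rep(c("a", "b"), c(3, 5)), rep(c("a", "b"), c(3, 5)))
  expect_equal(ev2$overall, 100)
  expect_equal(unname(ev2$per_class), c(100, 100))
  # per-class accuracies recompose the overall accuracy
  truth <- rep(c("a", "b"), c(6, 2))
  pred <- c("a", "a", "b", "a", "b", "a", "b", "a")
  ev3 <- evaluate_predictions(truth, pred)
  sizes <- table(truth)[names(ev3$per_class)]
  expect_equal(sum(ev3$per_class * as.numeric(sizes)) / length(truth), ev3$overall)
  expect_error(evaluate_predictions(c("a", "b"), c("a", "c")),
               class = "reporting_error")
})
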
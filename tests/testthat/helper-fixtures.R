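# Shared fixtures, built in code.

# deterministic random RGB image
random_image <- function(h = 8, w = 8, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

random_gray <- function(h = 8, w = 8, seed = 1, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}

# random histogram over a limited number of populated levels
random_histogram <- function(seed, n_levels = 16) {
  set.seed(seed)
  p <- numeric(256)
  idx <- sample(1:256, n_levels)
  p[idx] <- stats::runif(n_levels)
  p / sum(p)
}

# independent exhaustive threshold oracle, straight from the definitions:
# background = levels <= T, object = levels > T
otsu_oracle <- function(p) {
  lev <- 0:255
  best_g <- -Inf; best_t <- NA_integer_
  for (tt in 0:255) {
    w1 <- sum(p[lev <= tt]); w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    mu1 <- sum(lev[lev <= tt] * p[lev <= tt]) / w1
    mu2 <- sum(lev[lev > tt] * p[lev > tt]) / w2
    g <- w1 * w2 * (mu2 - mu1)^2
    if (g > best_g + 1e-15) { best_g <- g; best_t <- tt }
  }
  list(threshold = best_t, g = best_g)
}

# brute-force median filter with reflect padding
median_oracle <- function(img, window) {
  h <- (window - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  refl <- function(n) { i <- seq_len(n); c(rev(i), i, rev(i))[(n - h + 1):(2 * n + h)] }
  pad <- img[refl(H), refl(W)]
  out <- img
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- stats::median(pad[i:(i + 2 * h), j:(j + 2 * h)])
  out
}

# small balanced two-class toy set
toy_binary <- function(n = 20, p = 5, seed = 7, sep = 2) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n / 2 * p, -sep), n / 2, p),
             matrix(stats::rnorm(n / 2 * p, sep), n / 2, p))
  list(X = X, y = rep(c("a", "b"), each = n / 2))
}

# tiny standard population for pipeline-level tests (n = 60)
small_population <- function(seed = 42) {
  make_feature_population(population_spec(n_per_cell = 10L, seed = seed),
                          certify = FALSE)
}
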
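# Row-wise pre-processing of pseudo-spectra. Savitzky-Golay smoothing
# (degree 2, 33-point window by default) is the selected method; standard
# normal variate, min-max and total-area normalization and polynomial
# baseline correction are available alternatives. Everything is fitted per
# row, so no training-set statistics leak into test rows.

# Apply f (vector -> vector) to each row of a feature_matrix or matrix.
apply_rows <- function(X, f) {
  if (inherits(X, "feature_matrix")) {
    out <- X
    out$X <- t(apply(X$X, 1L, f))
    rownames(out$X) <- X$sample_id
    colnames(out$X) <- colnames(X$X)
    return(out)
  }
  Y <- t(apply(as.matrix(X), 1L, f))
  dimnames(Y) <- dimnames(X)
  Y
}

#' Savitzky-Golay smoothing weights and projection
#'
#' Least-squares polynomial smoothing over a symmetric window: the
#' projection matrix `P = A (A'A)^{-1} A'` onto polynomials of the given
#' degree evaluated at offsets `-h..h`. The centre row of `P` is the usual
#' convolution kernel for interior points; the first/last `h` rows evaluate
#' the edge windows' fitted polynomials at the edge positions.
#'
#' @param window Odd window length.
#' @param degree Polynomial degree, `< window`.
#' @return `window x window` projection matrix.
#' @keywords internal
savgol_projection <- function(window, degree) {
  h <- (window - 1L) %/% 2L
  A <- outer(seq(-h, h), 0:degree, `^`)
  A %*% solve(crossprod(A), t(A))
}

savgol_vector <- function(x, window, degree) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  P <- savgol_projection(window, degree)
  y <- numeric(n)
  mid <- P[h + 1L, ]
  for (i in (h + 1L):(n - h)) y[i] <- sum(mid * x[(i - h):(i + h)])
  # edges: evaluate the nearest full window's polynomial fit at edge offsets
  y[1:h] <- (P %*% x[1:window])[1:h]
  y[(n - h + 1L):n] <- (P %*% x[(n - window + 1L):n])[(window - h + 1L):window]
  y
}

#' Savitzky-Golay smoothing of feature rows
#'
#' Smooths each row independently by local least-squares polynomial fitting.
#' Defaults follow the selected pre-processing: a degree-2 polynomial over a
#' 33-point moving window. Polynomials of degree `<= degree` pass through
#' unchanged. Labels are untouched.
#'
#' @param X A `feature_matrix`, or a numeric matrix (rows = samples).
#' @param window Odd window length, `<=` row length.
#' @param degree Polynomial degree, `< window`.
#' @return Smoothed object of the same type as `X`.
#' @export
savgol_smooth <- function(X, window = 33L, degree = 2L) {
  p <- if (inherits(X, "feature_matrix")) ncol(X$X) else ncol(as.matrix(X))
  if (length(window) != 1L || window %% 2L == 0L || window < 3L)
    rc_error("invalid_parameter", "window must be odd and >= 3")
  if (window > p)
    rc_error("invalid_parameter", "window exceeds the number of variables")
  if (degree >= window || degree < 0)
    rc_error("invalid_parameter", "degree must satisfy 0 <= degree < window")
  apply_rows(X, function(r) savgol_vector(r, window, degree))
}

#' Row-wise normalization of feature matrices
#'
#' * `snv`: standard normal variate, `(x - mean) / sd` (rows get mean 0,
#'   unit sample standard deviation);
#' * `minmax`: rescale each row to span `[0, 1]`;
#' * `area`: divide each row by its sum so rows integrate to 1.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param mode One of `"snv"`, `"minmax"`, `"area"`.
#' @return Normalized object of the same type as `X`.
#' @export
normalize_rows <- function(X, mode = c("snv", "minmax", "area")) {
  mode <- match.arg(mode)
  f <- switch(mode,
    snv = function(r) {
      s <- stats::sd(r)
      if (s == 0) rc_error("degenerate_input", "zero-variance row under snv")
      (r - mean(r)) / s
    },
    minmax = function(r) {
      rng <- range(r)
      if (diff(rng) == 0) rc_error("degenerate_input", "constant row under minmax")
      (r - rng[1]) / diff(rng)
    },
    area = function(r) {
      s <- sum(r)
      if (s == 0) rc_error("degenerate_input", "zero-sum row under area normalization")
      r / s
    })
  apply_rows(X, f)
}

#' Polynomial baseline correction of feature rows
#'
#' Fits a least-squares polynomial of the given degree to each row (over
#' the variable index) and subtracts it; degree 0 removes the row mean.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param degree Baseline polynomial degree, >= 0.
#' @return Corrected object of the same type as `X`.
#' @export
baseline_correct <- function(X, degree = 2L) {
  if (length(degree) != 1L || degree < 0)
    rc_error("invalid_parameter", "degree must be >= 0")
  p <- if (inherits(X, "feature_matrix")) ncol(X$X) else ncol(as.matrix(X))
  idx <- seq_len(p)
  B <- if (degree == 0) matrix(1, p, 1) else cbind(1, stats::poly(idx, degree))
  H <- B %*% solve(crossprod(B), t(B))
  apply_rows(X, function(r) as.numeric(r - H %*% r))
}

#' Apply a named pre-processing method
#'
#' Dispatcher used by the pipeline: `none`, `savgol` (default parameters
#' `window = 33`, `degree = 2`), `snv`, `minmax`, `area` or `baseline`.
#'
#' @param X A `feature_matrix` or numeric matrix.
#' @param method Method name.
#' @param ... Passed on to the specific method.
#' @return Pre-processed object of the same type as `X`.
#' @export
preprocess <- function(X, method = c("savgol", "none", "snv", "minmax", "area",
                                     "baseline"), ...) {
  method <- match.arg(method)
  switch(method,
         none = X,
         savgol = savgol_smooth(X, ...),
         snv = normalize_rows(X, "snv"),
         minmax = normalize_rows(X, "minmax"),
         area = normalize_rows(X, "area"),
         baseline = baseline_correct(X, ...))
}
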
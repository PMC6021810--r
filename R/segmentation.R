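# Rainbow-patch segmentation: grayscale conversion, median filtering, Otsu
# thresholding, saturation gating, morphological clean-up and
# connected-component selection, ending in a standardized 100x100 RGB crop.

rc_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

#' Convert an RGB image to grayscale
#'
#' Weighted channel combination `round(wR*R + wG*G + wB*B)`, clipped to
#' 0--255. The segmentation default is the standard luminance weighting
#' (0.299, 0.587, 0.114); feature extraction uses its own weights (see
#' [combine_channels()]).
#'
#' @param img `H x W x 3` array, values 0--255.
#' @param weights Length-3 non-negative weights (R, G, B) with positive sum.
#' @return `H x W` matrix of integer gray levels.
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  img <- as_raw_image(img)
  if (length(weights) != 3L || anyNA(weights) || any(weights < 0) || sum(weights) <= 0)
    rc_error("invalid_parameter", "grayscale weights must be non-negative with positive sum")
  g <- weights[1] * img[, , 1] + weights[2] * img[, , 2] + weights[3] * img[, , 3]
  pmin(pmax(round(g), 0), 255)
}

# Reflect (mirror, edge included) index vector for padding a length-n axis
# by h on each side: d c b a | a b c d | d c b a ...
reflect_idx <- function(n, h) {
  idx <- seq_len(n)
  reps <- c(rev(idx), idx, rev(idx))
  # take the window of length n + 2h centred on the middle copy
  reps[(n - h + 1):(2 * n + h)]
}

#' Median filter a grayscale image
#'
#' Each output pixel is the median of its `window x window` neighbourhood;
#' edges use reflect padding. Eliminates isolated (salt/pepper) noise while
#' preserving edges.
#'
#' @param img `H x W` matrix.
#' @param window Odd window side length, >= 1.
#' @return Filtered matrix, same shape.
#' @export
median_filter <- function(img, window = 3L) {
  img <- as_gray_image(img)
  if (length(window) != 1L || window < 1L || window %% 2L == 0L)
    rc_error("invalid_parameter", "median filter window must be odd and >= 1")
  if (window == 1L) return(img)
  h <- (window - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  if (window > 2 * min(H, W))
    rc_error("invalid_parameter", "median filter window too large for image")
  pad <- img[reflect_idx(H, h), reflect_idx(W, h), drop = FALSE]
  w2 <- window * window
  stack <- matrix(0, H * W, w2)
  k <- 1L
  for (dj in 0:(window - 1L)) for (di in 0:(window - 1L)) {
    stack[, k] <- pad[di + seq_len(H), dj + seq_len(W)]
    k <- k + 1L
  }
  mid <- (w2 + 1L) %/% 2L
  med <- apply(stack, 1L, function(r) sort.int(r, method = "quick")[mid])
  matrix(med, H, W)
}

#' Gray-level histogram as probabilities
#'
#' @param img `H x W` matrix of integer gray levels 0--255.
#' @return Numeric vector of 256 probabilities (class `gray_histogram`),
#'   summing to one; element `i + 1` is the probability of level `i`.
#' @export
gray_histogram <- function(img) {
  img <- as_gray_image(img)
  if (length(img) == 0L) rc_error("invalid_input", "empty image")
  p <- tabulate(as.integer(round(img)) + 1L, nbins = 256L) / length(img)
  structure(p, class = "gray_histogram", names = 0:255)
}

#' Between-class variance criterion for all candidate thresholds
#'
#' For each candidate threshold `T` (0--255) with background class at levels
#' `<= T` and object class at levels `> T`, computes the class probabilities
#' `omega1`, `omega2`, class means `mu1`, `mu2`, the global mean
#' `mu = omega1*mu1 + omega2*mu2`, and the separability criterion either as
#' the weighted squared deviation of the class means from the global mean
#' (`"decomposed"`) or the algebraically identical product form
#' `omega1*omega2*(mu2 - mu1)^2` (`"product"`).
#'
#' @param hist A `gray_histogram` (or any 256-vector of probabilities).
#' @param formula Which algebraic form of the criterion to evaluate.
#' @return Length-256 vector `g(T)`; `NA` where either class is empty.
#' @export
otsu_criterion <- function(hist, formula = c("product", "decomposed")) {
  formula <- match.arg(formula)
  p <- as.numeric(hist)
  stopifnot(length(p) == 256L)
  lev <- 0:255
  omega1 <- cumsum(p)
  m1cum <- cumsum(lev * p)
  mu_tot <- m1cum[256]
  omega2 <- 1 - omega1
  valid <- omega1 > 0 & omega2 > 0
  mu1 <- ifelse(valid, m1cum / omega1, NA_real_)
  mu2 <- ifelse(valid, (mu_tot - m1cum) / omega2, NA_real_)
  g <- if (formula == "product") {
    omega1 * omega2 * (mu2 - mu1)^2
  } else {
    omega1 * (mu1 - mu_tot)^2 + omega2 * (mu2 - mu_tot)^2
  }
  g[!valid] <- NA_real_
  g
}

#' Automatic threshold selection by between-class variance maximization
#'
#' Scans every candidate threshold and returns the one maximizing the
#' between-class variance (equivalently, minimizing the weighted
#' within-class variance). Ties are broken toward the smallest threshold.
#'
#' @param hist A `gray_histogram`.
#' @return List of class `otsu_result` with elements `threshold` (integer
#'   in 0--255), `criterion` (length-256 vector of `g(T)`, `NA` where a
#'   class is empty) and `class_stats` (`omega1`, `omega2`, `mu1`, `mu2`,
#'   `mu` at the optimum).
#' @export
otsu_threshold <- function(hist) {
  p <- as.numeric(hist)
  if (length(p) != 256L || anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    rc_error("invalid_input", "histogram must be 256 non-negative probabilities summing to 1")
  if (sum(p > 0) < 2L)
    rc_error("degenerate_input", "histogram has fewer than two populated gray levels")
  g <- otsu_criterion(p, "product")
  t_opt <- which.max(g) - 1L # which.max skips NA, returns first (smallest T)
  lev <- 0:255
  omega1 <- sum(p[lev <= t_opt])
  omega2 <- 1 - omega1
  mu1 <- sum(lev[lev <= t_opt] * p[lev <= t_opt]) / omega1
  mu2 <- sum(lev[lev > t_opt] * p[lev > t_opt]) / omega2
  structure(list(
    threshold = t_opt,
    criterion = g,
    class_stats = list(omega1 = omega1, omega2 = omega2, mu1 = mu1, mu2 = mu2,
                       mu = omega1 * mu1 + omega2 * mu2)
  ), class = "otsu_result")
}

#' Threshold a grayscale image into a binary object mask
#'
#' Object pixels are those strictly greater than `threshold`.
#'
#' @param img `H x W` matrix.
#' @param threshold Integer in 0--255.
#' @return Logical `H x W` matrix (`TRUE` = object).
#' @export
binarize <- function(img, threshold) {
  img <- as_gray_image(img)
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 255)
    rc_error("invalid_parameter", "threshold must lie in [0, 255]")
  img > threshold
}

shift_logical <- function(m, di, dj, fill = FALSE) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  src_r <- seq_len(H) - di; src_c <- seq_len(W) - dj
  ok_r <- src_r >= 1 & src_r <= H; ok_c <- src_c >= 1 & src_c <= W
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

disk_offsets <- function(radius) {
  d <- expand.grid(di = -radius:radius, dj = -radius:radius)
  d[d$di^2 + d$dj^2 <= radius^2, , drop = FALSE]
}

erode_mask <- function(mask, off) {
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out & shift_logical(mask, off$di[k], off$dj[k], fill = FALSE)
  out
}

dilate_mask <- function(mask, off) {
  out <- mask
  for (k in seq_len(nrow(off)))
    out <- out | shift_logical(mask, off$di[k], off$dj[k], fill = FALSE)
  out
}

#' Morphological clean-up of a binary mask
#'
#' Binary opening (erosion then dilation) followed by closing (dilation then
#' erosion) with a disk structuring element: opening removes specks smaller
#' than the disk, closing fills comparable holes. `radius = 0` is the
#' identity.
#'
#' @param mask Logical matrix.
#' @param radius Disk radius in pixels, >= 0.
#' @return Cleaned logical matrix.
#' @export
morphological_clean <- function(mask, radius = 1L) {
  if (!is.matrix(mask) || !is.logical(mask))
    rc_error("invalid_input", "mask must be a logical matrix")
  if (length(radius) != 1L || is.na(radius) || radius < 0)
    rc_error("invalid_parameter", "radius must be >= 0")
  if (radius == 0) return(mask)
  off <- disk_offsets(radius)
  opened <- dilate_mask(erode_mask(mask, off), off)
  erode_mask(dilate_mask(opened, off), off)
}

#' Label 4-connected components of a binary mask
#'
#' Iterative minimum-label propagation over the 4-neighbourhood; suitable
#' for the compact blob-like objects this package segments.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of the same shape: 0 for background, components
#'   numbered 1, 2, ... in order of their smallest linear pixel index.
#' @export
label_components <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    rc_error("invalid_input", "mask must be a logical matrix")
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(as.numeric(seq_len(H * W)), H, W)
  lab[!mask] <- Inf
  if (!any(mask)) return(matrix(0L, H, W))
  repeat {
    up    <- rbind(lab[-1, , drop = FALSE], Inf)
    down  <- rbind(Inf, lab[-H, , drop = FALSE])
    left  <- cbind(lab[, -1, drop = FALSE], Inf)
    right <- cbind(Inf, lab[, -W, drop = FALSE])
    new <- pmin(lab, up, down, left, right)
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  roots <- sort(unique(lab[is.finite(lab)]))
  out <- matrix(0L, H, W)
  out[mask] <- match(lab[mask], roots)
  out
}

#' Per-pixel saturation of an RGB image
#'
#' HSV saturation on the 0--1 scale, used to gate out the low-saturation
#' (gray/white) background before component selection.
#'
#' @param img `H x W x 3` array.
#' @return `H x W` matrix of saturations in `[0, 1]`.
#' @export
saturation_map <- function(img) {
  img <- as_raw_image(img)
  hsv <- grDevices::rgb2hsv(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
                            b = as.vector(img[, , 3]), maxColorValue = 255)
  matrix(hsv["s", ], nrow = dim(img)[1], ncol = dim(img)[2])
}

#' Bilinear resampling of a matrix
#'
#' @param m Input matrix.
#' @param out_h,out_w Output dimensions.
#' @return `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(m, out_h, out_w) {
  H <- nrow(m); W <- ncol(m)
  # map output pixel centres onto input pixel-centre coordinates
  yi <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h + 0.5, 1), H)
  xi <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w + 0.5, 1), W)
  y0 <- if (H > 1) pmin(floor(yi), H - 1) else rep(1, out_h)
  x0 <- if (W > 1) pmin(floor(xi), W - 1) else rep(1, out_w)
  fy <- yi - y0; fx <- xi - x0
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  a <- m[y0, x0, drop = FALSE]; b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]; d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

#' Segmentation settings
#'
#' @param gray_weights RGB weights for the grayscale step.
#' @param median_window Odd median-filter window.
#' @param use_hsv Gate the threshold mask on saturation.
#' @param saturation_min Minimum HSV saturation (0--1 scale) for object
#'   pixels when `use_hsv` is `TRUE`.
#' @param morph_radius Disk radius of the morphological clean-up.
#' @param patch_size Output patch side length.
#' @return List of settings.
#' @export
segmentation_config <- function(gray_weights = c(0.299, 0.587, 0.114),
                                median_window = 3L,
                                use_hsv = TRUE,
                                saturation_min = 0.15,
                                morph_radius = 1L,
                                patch_size = 100L) {
  list(gray_weights = gray_weights, median_window = median_window,
       use_hsv = use_hsv, saturation_min = saturation_min,
       morph_radius = morph_radius, patch_size = patch_size)
}

#' Extract one standardized rainbow patch from a photograph
#'
#' Full segmentation pipeline: grayscale conversion, median filtering,
#' automatic thresholding on the filtered image, optional saturation gate,
#' morphological clean-up, selection of a single connected component
#' (largest area, ties broken by leftmost then topmost bounding box), crop
#' of the RGB bounding box, rotation so the long axis (the dispersion axis)
#' runs along rows, and bilinear resampling to `patch_size x patch_size`.
#'
#' @param img `H x W x 3` array, values 0--255.
#' @param cfg Settings from [segmentation_config()].
#' @return List of class `rainbow_patch`: `pixels`
#'   (`patch_size x patch_size x 3` integer array), `source_bbox`
#'   (`rmin, rmax, cmin, cmax` in the original image), `rotated` (logical),
#'   `threshold` (the selected gray threshold).
#' @export
extract_rainbow <- function(img, cfg = segmentation_config()) {
  img <- as_raw_image(img)
  gray <- to_grayscale(img, cfg$gray_weights)
  den <- median_filter(gray, cfg$median_window)
  ot <- tryCatch(otsu_threshold(gray_histogram(den)),
                 degenerate_input = function(e) NULL)
  if (is.null(ot))
    rc_error("segmentation_failure", "image has a single gray level; no object found",
             mask = matrix(FALSE, nrow(gray), ncol(gray)))
  mask <- binarize(den, ot$threshold)
  if (isTRUE(cfg$use_hsv))
    mask <- mask & (saturation_map(img) >= cfg$saturation_min)
  mask <- morphological_clean(mask, cfg$morph_radius)
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp == 0L)
    rc_error("segmentation_failure", "no connected component above threshold",
             mask = mask)
  # largest area; ties: leftmost bounding box, then topmost
  stats <- do.call(rbind, lapply(seq_len(ncomp), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(area = nrow(w), cmin = min(w[, 2]), rmin = min(w[, 1]),
      rmax = max(w[, 1]), cmax = max(w[, 2]))
  }))
  ord <- order(-stats[, "area"], stats[, "cmin"], stats[, "rmin"])
  sel <- stats[ord[1], ]
  rows <- sel["rmin"]:sel["rmax"]; cols <- sel["cmin"]:sel["cmax"]
  crop <- img[rows, cols, , drop = FALSE]
  rotated <- length(cols) > length(rows)
  if (rotated) crop <- aperm(crop, c(2, 1, 3)) # long axis -> rows
  s <- cfg$patch_size
  out <- array(0, dim = c(s, s, 3))
  for (k in 1:3) out[, , k] <- resize_bilinear(crop[, , k], s, s)
  out <- pmin(pmax(round(out), 0), 255)
  structure(list(pixels = out,
                 source_bbox = c(rmin = unname(sel["rmin"]), rmax = unname(sel["rmax"]),
                                 cmin = unname(sel["cmin"]), cmax = unname(sel["cmax"])),
                 rotated = rotated,
                 threshold = ot$threshold),
            class = "rainbow_patch")
}
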
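# Synthetic fixtures: (a) photographs of diffraction rainbow patches on a
# dark background with ground truth for the segmentation stage; (b) feature
# populations with three linearly separable species groups (signal confined
# to variables 40-60) and an organic/non-organic labelling generated by a
# nonlinear (radial) rule on two latent factors, so the linear classifier
# cannot separate the types while kernel/local models can.

#' Scene specification for a synthetic rainbow photograph
#'
#' @param width,height Image size in pixels.
#' @param center Patch centre `c(row, col)`.
#' @param axes Ellipse semi-axes `c(long, short)` in pixels; the long axis
#'   is the dispersion axis.
#' @param rotation Patch rotation in degrees (0 = long axis vertical).
#' @param n_patches 1, or 2 for a symmetric pair mirrored about the image's
#'   vertical midline.
#' @param profile Per-channel spectral profile along the dispersion axis:
#'   list of `R`, `G`, `B`, each `c(center, width, amp)` with `center`,
#'   `width` on the 0--1 axis position scale and `amp` in 0--255.
#' @param glow Broadband intensity floor (counts) added to every channel
#'   inside the ellipse, keeping the patch bright end to end;
#'   `glow + amp` must stay `<= 255`.
#' @param background Mean background level (counts).
#' @param noise_sd Gaussian sensor noise standard deviation (counts).
#' @param sp_rate Salt-and-pepper pixel rate.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 160L, height = 120L,
                       center = c(60, 55), axes = c(45, 16), rotation = 0,
                       n_patches = 1L,
                       profile = list(R = c(0.12, 0.14, 160),
                                      G = c(0.50, 0.16, 150),
                                      B = c(0.88, 0.14, 165)),
                       glow = 90,
                       background = 3, noise_sd = 3, sp_rate = 0.002,
                       seed = 42L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               center = center, axes = axes, rotation = rotation,
               n_patches = as.integer(n_patches), profile = profile,
               glow = glow, background = background, noise_sd = noise_sd,
               sp_rate = sp_rate, seed = as.integer(seed))
  if (any(vapply(profile, function(p) p[3], numeric(1)) + glow > 255))
    rc_error("invalid_spec", "glow plus profile amplitude must be <= 255")
  spec$centers <- if (spec$n_patches == 1L) list(center) else
    list(center, c(center[1], width + 1 - center[2]))
  half <- max(axes) + 2
  for (ct in spec$centers) {
    if (ct[1] - half < 1 || ct[1] + half > height ||
        ct[2] - half < 1 || ct[2] + half > width)
      rc_error("invalid_spec", "patch does not fit inside the image frame")
  }
  structure(spec, class = "scene_spec")
}

# Render one elliptical rainbow patch into channel matrices (in place).
# `glow` is a broadband (white) floor added across the whole ellipse so the
# patch is bright and saturated along its entire length, as in a
# photographed rainbow under a dark-room flashlight.
render_patch <- function(chan, ct, axes, rotation, profile, glow) {
  H <- nrow(chan[[1]]); W <- ncol(chan[[1]])
  th <- rotation * pi / 180
  rr <- matrix(seq_len(H), H, W) - ct[1]
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) - ct[2]
  a <- rr * cos(th) + cc * sin(th)   # along long axis
  b <- -rr * sin(th) + cc * cos(th)  # across
  inside <- (a / axes[1])^2 + (b / axes[2])^2 <= 1
  v <- (a + axes[1]) / (2 * axes[1]) # 0..1 position along dispersion axis
  for (k in c("R", "G", "B")) {
    pr <- profile[[k]]
    val <- glow + pr[3] * exp(-(v - pr[1])^2 / (2 * pr[2]^2))
    chan[[k]][inside] <- pmax(chan[[k]][inside], val[inside])
  }
  list(chan = chan, inside = inside)
}

#' Generate a synthetic rainbow photograph with ground truth
#'
#' Renders one (or two symmetric) smoothly colour-graded elliptical patches
#' on a dark background, then applies Gaussian sensor noise and
#' salt-and-pepper pixels. The ground truth carries the noiseless object
#' mask, the bounding box of the primary (leftmost) patch, and the true
#' pseudo-spectrum: the feature vector the extraction pipeline would
#' produce from the noiseless scene cropped at the true bounding box.
#'
#' @param spec A [scene_spec()].
#' @return List with `image` (`H x W x 3`), `mask` (noiseless object mask),
#'   `bbox` (`rmin, rmax, cmin, cmax` of the primary patch), `profile`
#'   (true length-100 pseudo-spectrum), and `spec`.
#' @export
make_rainbow_image <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  chan <- list(R = matrix(0, H, W), G = matrix(0, H, W), B = matrix(0, H, W))
  masks <- vector("list", length(spec$centers))
  for (i in seq_along(spec$centers)) {
    res <- render_patch(chan, spec$centers[[i]], spec$axes, spec$rotation,
                        spec$profile, spec$glow)
    chan <- res$chan
    masks[[i]] <- res$inside
  }
  clean <- array(0, dim = c(H, W, 3))
  for (k in 1:3) clean[, , k] <- pmin(pmax(chan[[k]] + spec$background, 0), 255)
  # primary patch = leftmost bounding box
  bboxes <- lapply(masks, function(m) {
    w <- which(m, arr.ind = TRUE)
    c(rmin = min(w[, 1]), rmax = max(w[, 1]), cmin = min(w[, 2]), cmax = max(w[, 2]))
  })
  primary <- which.min(vapply(bboxes, `[[`, numeric(1), "cmin"))
  bbox <- bboxes[[primary]]
  # true pseudo-spectrum from the noiseless crop at the true bbox
  crop <- clean[bbox["rmin"]:bbox["rmax"], bbox["cmin"]:bbox["cmax"], , drop = FALSE]
  if (dim(crop)[2] > dim(crop)[1]) crop <- aperm(crop, c(2, 1, 3))
  patch <- array(0, dim = c(100, 100, 3))
  for (k in 1:3) patch[, , k] <- resize_bilinear(crop[, , k], 100, 100)
  truth_profile <- row_means(combine_channels(pmin(pmax(round(patch), 0), 255)))
  img <- clean
  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  if (spec$sp_rate > 0) {
    npx <- H * W
    hit <- which(stats::runif(npx) < spec$sp_rate)
    val <- ifelse(stats::runif(length(hit)) < 0.5, 0, 255)
    for (k in 1:3) {
      m <- img[, , k]
      m[hit] <- val
      img[, , k] <- m
    }
  }
  img <- pmin(pmax(round(img), 0), 255)
  mask <- Reduce(`|`, masks)
  list(image = img, mask = mask, bbox = bbox, profile = truth_profile,
       spec = spec)
}

#' Population specification for synthetic feature matrices
#'
#' The stated world: 150 samples, three species of 50 (25 organic + 25
#' non-organic each). Species differ by Gaussian mean bumps confined to
#' variables 40--60 (linearly separable); the organic/non-organic labelling
#' comes from a radial rule on two latent factors embedded smoothly at
#' variables ~25 and ~75, so the two types interleave and are not linearly
#' separable.
#'
#' @param n_per_cell Samples per species x type cell (>= 2).
#' @param species_centers Bump centre variable index per species.
#' @param species_width,species_amp Bump width (variables) and height
#'   (counts).
#' @param ring_inner Organic samples draw latent radii in
#'   `[0.2, ring_inner]`; non-organic in `[ring_outer, ring_max]`.
#' @param ring_outer,ring_max See `ring_inner`.
#' @param latent_amp Scale (counts) of the latent-factor embedding.
#' @param noise_sd Additive Gaussian noise (counts, 0--255 scale).
#' @param seed Integer seed.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(n_per_cell = 25L,
                            species_centers = c(Gala = 44, `Pink lady` = 50,
                                                Braeburn = 56),
                            species_width = 3, species_amp = 25,
                            ring_inner = 0.95, ring_outer = 1.2,
                            ring_max = 1.9, latent_amp = 20,
                            noise_sd = 2.0, seed = 42L) {
  if (n_per_cell < 2L) rc_error("invalid_spec", "need >= 2 samples per cell")
  if (!(ring_inner > 0 && ring_outer > ring_inner && ring_max > ring_outer))
    rc_error("invalid_spec", "ring radii must satisfy 0 < inner < outer < max")
  structure(list(n_per_cell = as.integer(n_per_cell),
                 species_centers = species_centers,
                 species_width = species_width, species_amp = species_amp,
                 ring_inner = ring_inner, ring_outer = ring_outer,
                 ring_max = ring_max, latent_amp = latent_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "population_spec")
}

#' Generate a synthetic feature population
#'
#' See [population_spec()] for the generating model. With `certify = TRUE`
#' (the default) the nonlinearity certificate is checked at generation
#' time: a linear PLS-DA LOOCV over 1--10 latent variables on the
#' organic/non-organic labels must stay below `ceiling_pct`, otherwise
#' generation fails. This makes downstream comparisons between linear and
#' nonlinear classifiers meaningful.
#'
#' @param spec A [population_spec()].
#' @param certify Assert the linear-inseparability certificate.
#' @param ceiling_pct Linear LOOCV accuracy ceiling (percent).
#' @return List with `fm` (a `feature_matrix` with `species` and `type`
#'   labels), `params` (latent factors, radii, generating curves) and,
#'   when certified, `linear_ceiling` (the measured linear LOOCV %).
#' @export
make_feature_population <- function(spec = population_spec(), certify = TRUE,
                                    ceiling_pct = 75) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  v <- seq_len(100)
  base <- 30 + 120 * exp(-(v - 50)^2 / (2 * 20^2))
  f1 <- exp(-(v - 25)^2 / (2 * 6^2))
  f2 <- exp(-(v - 75)^2 / (2 * 6^2))
  species <- names(spec$species_centers)
  if (is.null(species)) species <- paste0("species", seq_along(spec$species_centers))
  rows <- list(); sp_lab <- character(0); ty_lab <- character(0)
  z_all <- NULL
  for (si in seq_along(spec$species_centers)) {
    bump <- spec$species_amp *
      exp(-(v - spec$species_centers[si])^2 / (2 * spec$species_width^2))
    for (ty in c("organic", "non-organic")) {
      n <- spec$n_per_cell
      r <- if (ty == "organic") {
        sqrt(stats::runif(n, 0.2^2, spec$ring_inner^2))
      } else {
        sqrt(stats::runif(n, spec$ring_outer^2, spec$ring_max^2))
      }
      ang <- stats::runif(n, 0, 2 * pi)
      z1 <- r * cos(ang); z2 <- r * sin(ang)
      cell <- t(vapply(seq_len(n), function(i) {
        base + bump + spec$latent_amp * (z1[i] * f1 + z2[i] * f2)
      }, numeric(100)))
      rows[[length(rows) + 1L]] <- cell
      sp_lab <- c(sp_lab, rep(species[si], n))
      ty_lab <- c(ty_lab, rep(ty, n))
      z_all <- rbind(z_all, cbind(z1, z2, r))
    }
  }
  X <- do.call(rbind, rows)
  if (spec$noise_sd > 0)
    X <- X + matrix(stats::rnorm(length(X), 0, spec$noise_sd), nrow(X), ncol(X))
  X <- pmin(pmax(X, 0), 255)
  fm <- feature_matrix(X, species = sp_lab, type = ty_lab)
  out <- list(fm = fm,
              params = list(z = z_all, base = base, f1 = f1, f2 = f2,
                            spec = spec))
  if (certify) {
    gs <- suppressWarnings(grid_search(fm, "plsda", list(n_lv = 1:10),
                                       response = "type"))
    if (gs$best_accuracy >= ceiling_pct)
      rc_error("invalid_spec",
               sprintf("nonlinearity certificate failed: linear LOOCV %.1f%% >= %.1f%%",
                       gs$best_accuracy, ceiling_pct))
    out$linear_ceiling <- gs$best_accuracy
  }
  out
}
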
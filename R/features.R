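# Pseudo-spectral feature extraction: weighted RGB combination of a
# standardized rainbow patch, then row means along the dispersion axis.

#' Combine RGB channels of a rainbow patch into one intensity matrix
#'
#' Per-pixel `F = W1*R + W2*G + W3*B`, kept as reals (no rounding). The
#' default weights (0.2, 0.7, 0.1) are the luminance ratios used for
#' feature extraction; they are deliberately distinct from the grayscale
#' weights used during segmentation.
#'
#' @param patch A `rainbow_patch` or a `100 x 100 x 3` array.
#' @param w Length-3 non-negative channel weights with positive sum.
#' @return `100 x 100` numeric matrix of combined intensities.
#' @export
combine_channels <- function(patch, w = c(0.2, 0.7, 0.1)) {
  px <- if (inherits(patch, "rainbow_patch")) patch$pixels else patch
  if (!is.array(px) || !identical(dim(px), c(100L, 100L, 3L)) &&
      !identical(dim(px), c(100, 100, 3)))
    rc_error("invalid_input", "patch must be a 100 x 100 x 3 array")
  if (length(w) != 3L || anyNA(w) || any(w < 0) || sum(w) <= 0)
    rc_error("invalid_parameter", "channel weights must be non-negative with positive sum")
  w[1] * px[, , 1] + w[2] * px[, , 2] + w[3] * px[, , 3]
}

#' Row means of a combined-intensity matrix
#'
#' Averages each row (the dispersion axis) of the `100 x 100` combined
#' intensity matrix, yielding the length-100 pseudo-spectrum.
#'
#' @param F_mat `100 x 100` numeric matrix.
#' @return Numeric vector of length 100.
#' @export
row_means <- function(F_mat) {
  if (!is.matrix(F_mat) || nrow(F_mat) != 100L || ncol(F_mat) != 100L)
    rc_error("invalid_input", "expected a 100 x 100 matrix")
  rowMeans(F_mat)
}

#' Construct a labelled feature matrix
#'
#' The package's central container: an `n x p` matrix of pseudo-spectra with
#' optional species and organic/non-organic type labels.
#'
#' @param X Numeric `n x p` matrix (no missing values).
#' @param species Optional length-`n` species labels.
#' @param type Optional length-`n` type labels (e.g. organic/non-organic).
#' @param sample_id Optional sample identifiers (default `s1, s2, ...`).
#' @return List of class `feature_matrix` with elements `X`, `species`,
#'   `type`, `sample_id`.
#' @export
feature_matrix <- function(X, species = NULL, type = NULL, sample_id = NULL) {
  X <- as.matrix(X)
  if (anyNA(X)) rc_error("invalid_input", "feature matrix contains missing values")
  n <- nrow(X)
  chk <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (length(v) != n) rc_error("labelling_error", paste(what, "labels must match row count"))
    if (anyNA(v)) rc_error("labelling_error", paste("missing", what, "label"))
    as.character(v)
  }
  if (is.null(sample_id)) sample_id <- paste0("s", seq_len(n))
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  rownames(X) <- sample_id
  structure(list(X = X, species = chk(species, "species"), type = chk(type, "type"),
                 sample_id = as.character(sample_id)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d samples x %d variables\n", nrow(x$X), ncol(x$X)))
  if (!is.null(x$species)) cat("  species:", paste(names(table(x$species)),
                                                   table(x$species), collapse = ", "), "\n")
  if (!is.null(x$type)) cat("  type:   ", paste(names(table(x$type)),
                                                table(x$type), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

# Row-subset a feature_matrix, keeping labels aligned.
fm_subset <- function(fm, idx) {
  feature_matrix(fm$X[idx, , drop = FALSE],
                 species = if (!is.null(fm$species)) fm$species[idx],
                 type = if (!is.null(fm$type)) fm$type[idx],
                 sample_id = fm$sample_id[idx])
}

#' Build a feature matrix from labelled rainbow patches
#'
#' Applies [combine_channels()] and [row_means()] to each patch; rows keep
#' the input order.
#'
#' @param patches List of `rainbow_patch` objects (or `100 x 100 x 3`
#'   arrays).
#' @param w Channel weights passed to [combine_channels()].
#' @param species,type,sample_id Optional per-patch labels.
#' @return A `feature_matrix` with one row per patch.
#' @export
build_feature_matrix <- function(patches, w = c(0.2, 0.7, 0.1),
                                 species = NULL, type = NULL, sample_id = NULL) {
  if (!length(patches)) rc_error("invalid_input", "no patches supplied")
  X <- t(vapply(patches, function(p) row_means(combine_channels(p, w)), numeric(100)))
  feature_matrix(X, species = species, type = type, sample_id = sample_id)
}

#' Write a feature matrix to CSV
#'
#' Columns `v1...vp`, then `species`, `type`, `sample_id` (label columns
#' only when present). Values are written at full precision so a
#' read/write round trip is lossless to well below 1e-9.
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$X)
  if (!is.null(fm$species)) df$species <- fm$species
  if (!is.null(fm$type)) df$type <- fm$type
  df$sample_id <- fm$sample_id
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' @param path CSV written by [write_feature_csv()] (or any CSV with
#'   numeric `v*` columns and optional `species`/`type`/`sample_id`).
#' @return A `feature_matrix`.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
  if (!length(vcols)) rc_error("invalid_input", "no feature columns (v1, v2, ...) found")
  X <- as.matrix(vapply(df[vcols], as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, vcols))
  feature_matrix(X,
                 species = if ("species" %in% names(df)) df$species,
                 type = if ("type" %in% names(df)) df$type,
                 sample_id = if ("sample_id" %in% names(df)) df$sample_id)
}
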
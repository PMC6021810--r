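#' Validate and coerce an RGB photograph array
#'
#' Images are plain integer arrays of dimension `H x W x 3` (RGB order) with
#' channel values in 0--255, the representation used throughout the package.
#'
#' @param x An `H x W x 3` numeric array.
#' @return The validated array, with storage mode integer-valued (double).
#' @export
as_raw_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("raw image must be an H x W x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("raw image must have at least one row and column", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("raw image channel values must lie in [0, 255]", call. = FALSE)
  x
}

#' Validate a grayscale image matrix
#'
#' @param x An `H x W` numeric matrix with values in 0--255.
#' @return The validated matrix.
#' @export
as_gray_image <- function(x) {
  if (!is.matrix(x))
    stop("gray image must be a matrix", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("gray values must lie in [0, 255]", call. = FALSE)
  x
}

# Tokenized header reader for Netpbm files: returns the next `n` whitespace
# separated tokens, skipping '#' comments.
ppm_tokens <- function(con, n) {
  out <- character(0)
  buf <- character(0)
  while (length(out) < n) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("unexpected end of Netpbm header", call. = FALSE)
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { out <- c(out, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  out
}

#' Read a Netpbm image (PGM/PPM)
#'
#' Reads ASCII (`P2`, `P3`) and binary (`P5`, `P6`) Netpbm images with a
#' maximum value of 255. Grayscale files return an `H x W` matrix, color
#' files an `H x W x 3` array.
#'
#' @param path Path to a `.pgm`/`.ppm` file.
#' @return Matrix or array of integer intensities in 0--255.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- ppm_tokens(con, 1L)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported Netpbm type: ", magic, call. = FALSE)
  hdr <- as.integer(ppm_tokens(con, 3L))
  w <- hdr[1]; h <- hdr[2]; maxval <- hdr[3]
  if (maxval != 255L) stop("only maxval 255 Netpbm files are supported", call. = FALSE)
  nchan <- if (magic %in% c("P3", "P6")) 3L else 1L
  npx <- w * h * nchan
  vals <- if (magic %in% c("P5", "P6")) {
    as.integer(readBin(con, "integer", n = npx, size = 1L, signed = FALSE))
  } else {
    as.integer(scan(con, what = integer(), n = npx, comment.char = "#", quiet = TRUE))
  }
  if (length(vals) != npx) stop("truncated Netpbm payload", call. = FALSE)
  if (nchan == 1L) {
    matrix(as.numeric(vals), nrow = h, ncol = w, byrow = TRUE)
  } else {
    # interleaved RGB, row-major
    a <- array(0, dim = c(h, w, 3L))
    m <- matrix(vals, ncol = 3L, byrow = TRUE)
    for (k in 1:3) a[, , k] <- matrix(m[, k], nrow = h, ncol = w, byrow = TRUE)
    a
  }
}

#' Write a Netpbm image (PGM/PPM)
#'
#' Writes an `H x W` matrix as PGM or an `H x W x 3` array as PPM. Logical
#' matrices (masks) are written as 0/255 PGM.
#'
#' @param img Matrix, logical matrix or `H x W x 3` array, values 0--255.
#' @param path Output path.
#' @param ascii Write ASCII (`P2`/`P3`) instead of binary (`P5`/`P6`).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, ascii = FALSE) {
  if (is.logical(img)) img <- matrix(as.numeric(img) * 255, nrow(img), ncol(img))
  is_color <- is.array(img) && length(dim(img)) == 3L
  vals <- if (is_color) {
    h <- dim(img)[1]; w <- dim(img)[2]
    as.vector(aperm(img, c(3, 2, 1))) # R,G,B interleaved, row-major
  } else {
    h <- nrow(img); w <- ncol(img)
    as.vector(t(img))
  }
  vals <- as.integer(round(vals))
  if (min(vals) < 0 || max(vals) > 255) stop("pixel values out of range", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  magic <- if (is_color) (if (ascii) "P3" else "P6") else (if (ascii) "P2" else "P5")
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(vals, collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(vals, con, size = 1L)
  }
  invisible(path)
}
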
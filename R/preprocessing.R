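# Image preprocessing chain applied before training/inference:
# grayscale conversion -> intensity normalization -> CLAHE -> gamma
# correction. All steps are deterministic and shape-preserving.

#' Preprocessing configuration
#'
#' @param clahe_clip_limit relative clip limit (multiples of the uniform
#'   tile histogram height); > 0.
#' @param clahe_tile_grid integer c(rows, cols) tiling of the image.
#' @param gamma positive exponent of the power-law correction.
#' @param normalize_mode `"min_max"` (range to [0,1]) or `"z_score"`.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(clahe_clip_limit = 2.0,
                              clahe_tile_grid = c(8L, 8L),
                              gamma = 1.2,
                              normalize_mode = c("min_max", "z_score")) {
  stopifnot(clahe_clip_limit > 0, gamma > 0, length(clahe_tile_grid) == 2L)
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = as.integer(clahe_tile_grid),
                 gamma = gamma,
                 normalize_mode = match.arg(normalize_mode)),
            class = "preprocess_config")
}

#' Read an image file as a numeric array
#'
#' PNG is read natively; JPEG requires the `jpeg` package. Values are scaled
#' to [0, 1]. TIFF is not supported in this build (no reader available
#' offline) and raises an error.
#'
#' @param path image file path.
#' @return (H, W) matrix for grayscale or (H, W, 3) array for RGB.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE)) {
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      }
      jpeg::readJPEG(path)
    },
    tif = ,
    tiff = stop("TIFF input is not supported in this build; convert to PNG",
                call. = FALSE),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(img)) == 3L && dim(img)[3L] == 1L) img <- img[, , 1L]
  img
}

#' Write a [0,1] grayscale matrix as PNG
#' @param img (H, W) matrix with values in [0, 1].
#' @param path output path.
#' @export
write_image <- function(img, path) {
  stopifnot(is.matrix(img))
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Convert to grayscale
#'
#' RGB input is reduced with standard luminance weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale input is returned unchanged.
#'
#' @param img (H, W) matrix or (H, W, 3) array.
#' @return (H, W) matrix.
#' @export
to_grayscale <- function(img) {
  d <- dim(img)
  if (is.matrix(img)) return(img)
  if (length(d) == 3L && d[3L] == 3L) {
    return(0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L])
  }
  stop("expected an (H, W) grayscale or (H, W, 3) RGB image", call. = FALSE)
}

#' Normalize image intensities
#'
#' `min_max` rescales to exactly [0, 1]; a constant image cannot be rescaled
#' and yields all zeros with a warning. `z_score` standardizes to mean 0 and
#' standard deviation 1 (population sd).
#'
#' @param img numeric matrix.
#' @param mode `"min_max"` or `"z_score"`.
#' @return numeric matrix of the same shape.
#' @export
normalize <- function(img, mode = c("min_max", "z_score")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(img), all(is.finite(img)))
  if (mode == "min_max") {
    rng <- range(img)
    if (rng[1L] == rng[2L]) {
      warning("constant image in min_max normalization; returning zeros")
      return(img * 0)
    }
    (img - rng[1L]) / (rng[2L] - rng[1L])
  } else {
    mu <- mean(img)
    sdv <- sqrt(mean((img - mu)^2))
    if (sdv == 0) {
      warning("constant image in z_score normalization; returning zeros")
      return(img * 0)
    }
    (img - mu) / sdv
  }
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clipping: each tile's 256-bin
#' histogram is clipped at `clip_limit` times the uniform bin height and the
#' excess is redistributed uniformly; pixel mappings are bilinearly
#' interpolated between the four neighbouring tile centres.
#'
#' @param img (H, W) matrix with values in [0, 1].
#' @param cfg a [preprocess_config()] (clip limit and tile grid are used).
#' @param nbins number of histogram bins.
#' @return equalized (H, W) matrix in [0, 1].
#' @export
apply_clahe <- function(img, cfg = preprocess_config(), nbins = 256L) {
  stopifnot(is.matrix(img))
  if (min(img) < 0 || max(img) > 1) {
    stop("apply_clahe expects intensities in [0, 1]", call. = FALSE)
  }
  h <- nrow(img); w <- ncol(img)
  nty <- cfg$clahe_tile_grid[1L]; ntx <- cfg$clahe_tile_grid[2L]
  bin <- pmin(floor(img * nbins) + 1L, nbins)
  # tile boundaries (as equal as possible)
  ys <- floor(seq(0L, h, length.out = nty + 1L))
  xs <- floor(seq(0L, w, length.out = ntx + 1L))
  luts <- array(0, c(nbins, nty, ntx))
  cy <- numeric(nty); cx <- numeric(ntx)
  for (ty in seq_len(nty)) {
    for (tx in seq_len(ntx)) {
      rows <- (ys[ty] + 1L):ys[ty + 1L]
      cols <- (xs[tx] + 1L):xs[tx + 1L]
      luts[, ty, tx] <- clahe_tile_lut(bin[rows, cols], nbins,
                                       cfg$clahe_clip_limit)
      cy[ty] <- mean(range(rows)); cx[tx] <- mean(range(cols))
    }
  }
  # bilinear interpolation between tile-centre mappings
  ri <- seq_len(h); ci <- seq_len(w)
  ty0 <- pmin(pmax(findInterval(ri, cy), 1L), nty - 1L)
  tx0 <- pmin(pmax(findInterval(ci, cx), 1L), ntx - 1L)
  if (nty == 1L) ty0 <- rep(1L, h)
  if (ntx == 1L) tx0 <- rep(1L, w)
  fy <- if (nty == 1L) rep(0, h) else
    pmin(pmax((ri - cy[ty0]) / (cy[ty0 + 1L] - cy[ty0]), 0), 1)
  fx <- if (ntx == 1L) rep(0, w) else
    pmin(pmax((ci - cx[tx0]) / (cx[tx0 + 1L] - cx[tx0]), 0), 1)
  ty1 <- if (nty == 1L) ty0 else ty0 + 1L
  tx1 <- if (ntx == 1L) tx0 else tx0 + 1L
  out <- matrix(0, h, w)
  bigty0 <- matrix(ty0, h, w); bigty1 <- matrix(ty1, h, w)
  bigtx0 <- matrix(tx0, h, w, byrow = TRUE)
  bigtx1 <- matrix(tx1, h, w, byrow = TRUE)
  bfy <- matrix(fy, h, w); bfx <- matrix(fx, h, w, byrow = TRUE)
  look <- function(ty, tx) luts[cbind(as.vector(bin), as.vector(ty),
                                      as.vector(tx))]
  v00 <- look(bigty0, bigtx0); v01 <- look(bigty0, bigtx1)
  v10 <- look(bigty1, bigtx0); v11 <- look(bigty1, bigtx1)
  out[] <- (1 - bfy) * ((1 - bfx) * v00 + bfx * v01) +
    bfy * ((1 - bfx) * v10 + bfx * v11)
  out
}

# clipped-histogram equalization lookup table for one tile of bin indices
clahe_tile_lut <- function(tile_bins, nbins, clip_limit) {
  n <- length(tile_bins)
  hist <- tabulate(tile_bins, nbins)
  clip <- max(clip_limit * n / nbins, 1)
  excess <- sum(pmax(hist - clip, 0))
  hist <- pmin(hist, clip) + excess / nbins
  cdf <- cumsum(hist) / n
  # map to [0, 1]; anchor so the lowest occupied bin maps near 0
  cdf
}

#' Gamma correction
#'
#' `out = in^gamma` on [0,1] intensities; monotone, with 0 and 1 as fixed
#' points; `gamma = 1` is the identity.
#'
#' @param img matrix with values in [0, 1].
#' @param gamma positive exponent.
#' @export
gamma_correct <- function(img, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive scalar", call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 1) {
    stop("gamma_correct expects intensities in [0, 1]", call. = FALSE)
  }
  img^gamma
}

#' Full preprocessing chain
#'
#' grayscale -> normalize -> CLAHE -> gamma, in the fixed listed order.
#' With `normalize_mode = "z_score"` the standardized image is affinely
#' rescaled back to [0, 1] before CLAHE (which is defined on [0, 1]).
#'
#' @param img raw image ((H, W) or (H, W, 3), [0,1] or 0-255 scale).
#' @param cfg a [preprocess_config()].
#' @return preprocessed (H, W) matrix in [0, 1].
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  g <- to_grayscale(img)
  if (max(g) > 1) g <- g / 255
  g <- normalize(g, cfg$normalize_mode)
  if (cfg$normalize_mode == "z_score") {
    rng <- range(g)
    g <- if (rng[1L] == rng[2L]) g * 0 else (g - rng[1L]) / (rng[2L] - rng[1L])
  }
  g <- apply_clahe(g, cfg)
  gamma_correct(pmin(pmax(g, 0), 1), cfg$gamma)
}
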
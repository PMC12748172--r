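# Procedural generator of fundus-like vessel images, masks and captions.
#
# Two modalities are emulated:
#   * cf   — color-fundus-like: a few thick trunks radiating from the
#            periphery toward the centre, plus a bright optic-disc blob;
#   * octa — OCTA-like: many fine trunks forming a dense mesh that spares a
#            central avascular disc (the foveal avascular zone).
# Vessel trees are recursive binary branchings of widened polyline segments;
# the binary mask is the rasterized tree; the image is the blurred,
# contrast-modulated mask plus seeded background noise. The caption is
# derived from descriptors measured on the mask, so text and pixels are
# consistent by construction.

#' Synthetic dataset configuration
#'
#' @param modality `"octa"` or `"cf"`.
#' @param size integer c(H, W); both at least 32.
#' @param n_trees number of peripheral seed points (trunks).
#' @param depth branching generations (0 = unbranched trunks).
#' @param width_decay multiplicative width factor per generation, in (0, 1).
#' @param trunk_width starting vessel half-width scale in pixels.
#' @param noise_sd background Gaussian noise sd (intensity units).
#' @param blur_sigma Gaussian blur sigma in pixels (0 disables blur).
#' @param fovea_radius_frac central avascular radius as a fraction of
#'   `min(size)/2`; only enforced for `octa`.
#' @param vessel_intensity peak vessel intensity in [0, 1].
#' @param p_abnormal probability that a sample carries one abnormal bright
#'   blob (image-only; never added to the mask).
#' @param density_cuts vessel-pixel-fraction cut points separating
#'   sparse/moderate/dense.
#' @param density_band plausibility band for the mask vessel fraction given
#'   this geometry; a generator contract checked in tests.
#' @param seed integer RNG seed; fixed seed implies fixed output.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(modality = c("octa", "cf"),
                         size = c(64L, 64L),
                         n_trees = NULL,
                         depth = NULL,
                         width_decay = 0.8,
                         trunk_width = NULL,
                         noise_sd = 0.08,
                         blur_sigma = 0.7,
                         fovea_radius_frac = 0.22,
                         vessel_intensity = 0.85,
                         p_abnormal = 0.25,
                         density_cuts = c(0.05, 0.15),
                         density_band = NULL,
                         seed = 1L) {
  modality <- match.arg(modality)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 32L)) {
    stop("size must be c(H, W) with both >= 32", call. = FALSE)
  }
  if (width_decay <= 0 || width_decay >= 1) {
    stop("width_decay must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(n_trees)) n_trees <- if (modality == "cf") 6L else 18L
  if (is.null(depth)) depth <- if (modality == "cf") 3L else 4L
  if (is.null(trunk_width)) trunk_width <- if (modality == "cf") 2.6 else 1.4
  if (is.null(density_band)) {
    density_band <- if (modality == "cf") c(0.01, 0.30) else c(0.05, 0.50)
  }
  structure(list(modality = modality, size = size, n_trees = as.integer(n_trees),
                 depth = as.integer(depth), width_decay = width_decay,
                 trunk_width = trunk_width, noise_sd = noise_sd,
                 blur_sigma = blur_sigma,
                 fovea_radius_frac = fovea_radius_frac,
                 vessel_intensity = vessel_intensity,
                 p_abnormal = p_abnormal, density_cuts = density_cuts,
                 density_band = density_band, seed = as.integer(seed)),
            class = "synth_config")
}

#' Grow a vessel tree as widened polyline segments
#'
#' Recursive binary branching from peripheral seed points toward the image
#' centre. Segment width is multiplied by `width_decay` each generation. In
#' `octa` mode no segment enters the central avascular disc. Consumes the
#' current RNG state; call `set.seed()` (or [generate_sample()], which seeds
#' from `cfg$seed`) for reproducibility.
#'
#' @param cfg a [synth_config()].
#' @return data.frame of segments: x0, y0, x1, y1, width, generation.
#' @export
grow_vessel_tree <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  h <- cfg$size[1L]; w <- cfg$size[2L]
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  faz_r <- if (cfg$modality == "octa") {
    cfg$fovea_radius_frac * min(h, w) / 2
  } else 0
  segs <- vector("list", 1024L); nseg <- 0L
  push <- function(x0, y0, x1, y1, wdt, gen) {
    nseg <<- nseg + 1L
    if (nseg > length(segs)) segs <<- c(segs, vector("list", length(segs)))
    segs[[nseg]] <<- c(x0, y0, x1, y1, wdt, gen)
  }
  seg_len0 <- 0.22 * min(h, w)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  grow <- function(x, y, ang, wdt, gen) {
    len <- seg_len0 * (0.75^gen) * stats::runif(1, 0.8, 1.2)
    ang <- ang + stats::runif(1, -0.25, 0.25)
    x1 <- x + len * cos(ang)
    y1 <- y + len * sin(ang)
    x1 <- clamp(x1, 1, w); y1 <- clamp(y1, 1, h)
    if (faz_r > 0) {
      # truncate the segment where it would cross the avascular boundary
      d1 <- sqrt((x1 - cx)^2 + (y1 - cy)^2)
      if (d1 < faz_r + wdt / 2 + 0.5) {
        d0 <- sqrt((x - cx)^2 + (y - cy)^2)
        lim <- faz_r + wdt / 2 + 0.75
        if (d0 <= lim) return(invisible(NULL))
        t_stop <- max((d0 - lim) / max(d0 - d1, 1e-9), 0)
        x1 <- x + t_stop * (x1 - x)
        y1 <- y + t_stop * (y1 - y)
        push(x, y, x1, y1, wdt, gen)
        return(invisible(NULL))
      }
    }
    push(x, y, x1, y1, wdt, gen)
    if (gen < cfg$depth) {
      spread <- stats::runif(1, 0.3, 0.7)
      wdt2 <- max(wdt * cfg$width_decay, 0.6)
      grow(x1, y1, ang - spread, wdt2, gen + 1L)
      grow(x1, y1, ang + spread, wdt2, gen + 1L)
    }
    invisible(NULL)
  }
  r0 <- 0.47 * min(h, w)
  for (t in seq_len(cfg$n_trees)) {
    theta <- stats::runif(1, 0, 2 * pi)
    x <- clamp(cx + r0 * cos(theta), 1, w)
    y <- clamp(cy + r0 * sin(theta), 1, h)
    ang_to_centre <- atan2(cy - y, cx - x)
    grow(x, y, ang_to_centre + stats::runif(1, -0.3, 0.3),
         cfg$trunk_width, 0L)
  }
  out <- do.call(rbind, segs[seq_len(nseg)])
  colnames(out) <- c("x0", "y0", "x1", "y1", "width", "generation")
  as.data.frame(out)
}

#' Rasterize segments into a binary mask
#' @param segs segment data.frame from [grow_vessel_tree()].
#' @param size integer c(H, W).
#' @return integer (H, W) matrix in {0, 1}.
#' @export
rasterize_tree <- function(segs, size) {
  h <- size[1L]; w <- size[2L]
  mask <- matrix(0L, h, w)
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    r <- s$width / 2
    xmin <- max(1L, floor(min(s$x0, s$x1) - r - 1))
    xmax <- min(w, ceiling(max(s$x0, s$x1) + r + 1))
    ymin <- max(1L, floor(min(s$y0, s$y1) - r - 1))
    ymax <- min(h, ceiling(max(s$y0, s$y1) + r + 1))
    xs <- xmin:xmax; ys <- ymin:ymax
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    dx <- s$x1 - s$x0; dy <- s$y1 - s$y0
    len2 <- dx * dx + dy * dy
    tt <- if (len2 < 1e-12) 0 else
      pmin(pmax(((px - s$x0) * dx + (py - s$y0) * dy) / len2, 0), 1)
    dist <- sqrt((px - (s$x0 + tt * dx))^2 + (py - (s$y0 + tt * dy))^2)
    blk <- mask[ys, xs, drop = FALSE]
    blk[dist <= r] <- 1L
    mask[ys, xs] <- blk
  }
  mask
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(h) + o, 1L), h)
    out <- out + k[o + r + 1L] * m[idx, , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (o in -r:r) {
    idx <- pmin(pmax(seq_len(w) + o, 1L), w)
    out2 <- out2 + k[o + r + 1L] * out[, idx, drop = FALSE]
  }
  out2
}

# radial blob (used for the optic disc and abnormal areas)
add_blob <- function(img, cy, cx, radius, intensity) {
  h <- nrow(img); w <- ncol(img)
  py <- matrix(seq_len(h), h, w)
  px <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (py - cy)^2 + (px - cx)^2
  img + intensity * exp(-d2 / (2 * (radius / 2)^2))
}

#' Density class from a mask
#' @param mask binary matrix.
#' @param cuts length-2 increasing cut points on the vessel-pixel fraction.
#' @export
density_class_of <- function(mask, cuts = c(0.05, 0.15)) {
  frac <- mean(mask == 1)
  if (frac < cuts[1L]) "sparse" else if (frac < cuts[2L]) "moderate" else "dense"
}

#' Generate one synthetic image/mask/label triple
#'
#' Seeds the RNG from `cfg$seed`, grows and rasterizes a vessel tree, builds
#' the intensity image (blur + contrast + noise + optic disc in `cf` mode),
#' and derives the text label from descriptors measured on the mask.
#' With `noise_sd = 0`, `blur_sigma = 0` and `p_abnormal = 0` in `octa`
#' mode, the image equals `vessel_intensity * mask` exactly.
#'
#' @param cfg a [synth_config()].
#' @param image_id file name recorded in the label (default derived from
#'   modality and seed).
#' @return object of class `synthetic_sample`: list(image, mask, label).
#' @export
generate_sample <- function(cfg, image_id = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  h <- cfg$size[1L]; w <- cfg$size[2L]
  segs <- grow_vessel_tree(cfg)
  mask <- rasterize_tree(segs, cfg$size)
  if (cfg$modality == "octa") {
    # hard guarantee: the central avascular disc carries no vessel pixels
    faz_r <- cfg$fovea_radius_frac * min(h, w) / 2
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    py <- matrix(seq_len(h), h, w)
    px <- matrix(seq_len(w), h, w, byrow = TRUE)
    mask[(py - cy)^2 + (px - cx)^2 < faz_r^2] <- 0L
  }
  img <- cfg$vessel_intensity * gaussian_blur(mask + 0, cfg$blur_sigma)
  abnormal <- character(0)
  if (cfg$modality == "cf") {
    disc_x <- w * stats::runif(1, 0.3, 0.7)
    disc_y <- h * stats::runif(1, 0.35, 0.65)
    img <- add_blob(img, disc_y, disc_x, 0.12 * min(h, w), 0.5)
  }
  if (stats::runif(1) < cfg$p_abnormal) {
    by <- stats::runif(1, 0.15, 0.85) * h
    bx <- stats::runif(1, 0.15, 0.85) * w
    img <- add_blob(img, by, bx, 0.09 * min(h, w), 0.35)
    vert <- if (by < h / 2) "upper" else "lower"
    horiz <- if (bx < w / 2) "left" else "right"
    abnormal <- paste(vert, horiz)
  }
  if (cfg$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, cfg$noise_sd), h, w)
  }
  img <- pmin(pmax(img, 0), 1)
  if (is.null(image_id)) {
    image_id <- sprintf("%s_%06d.png", cfg$modality, cfg$seed)
  }
  label <- text_label(
    image_id = image_id,
    density_class = density_class_of(mask, cfg$density_cuts),
    distribution_class = if (cfg$modality == "cf") "radial" else "reticular",
    abnormal_areas = abnormal)
  structure(list(image = img, mask = mask, label = label),
            class = "synthetic_sample")
}

#' Generate a dataset on disk
#'
#' Writes `images/*.png`, `masks/*.png`, `labels.csv` and `manifest.json`
#' under `out_dir`. Re-running with the same configuration reproduces
#' byte-identical label tables and pixel-identical images.
#'
#' @param cfg a [synth_config()]; per-sample seeds are derived from
#'   `cfg$seed`.
#' @param n_train,n_test split sizes.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly: list(train, test, n, config echo).
#' @export
generate_dataset <- function(cfg, n_train, n_test, out_dir) {
  stopifnot(n_train >= 0, n_test >= 0, n_train + n_test >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  n <- n_train + n_test
  labels <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i * 131L
    ids[i] <- sprintf("%s_%03d.png", cfg$modality, i)
    smp <- generate_sample(cfg_i, image_id = ids[i])
    write_image(smp$image, file.path(out_dir, "images", ids[i]))
    write_image(smp$mask + 0, file.path(out_dir, "masks", ids[i]))
    labels[[i]] <- smp$label
  }
  write_label_table(label_table(labels), file.path(out_dir, "labels.csv"))
  manifest <- list(modality = cfg$modality, size = cfg$size,
                   seed = cfg$seed, n_train = n_train, n_test = n_test,
                   train = ids[seq_len(n_train)],
                   test = if (n_test > 0) ids[n_train + seq_len(n_test)]
                          else character(0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir dataset directory.
#' @param split `"train"`, `"test"` or `"all"`.
#' @return list of samples: each list(image, mask, caption, image_id).
#' @export
load_dataset <- function(dir, split = c("train", "test", "all")) {
  split <- match.arg(split)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  tab <- read_label_table(file.path(dir, "labels.csv"))
  ids <- switch(split, train = manifest$train, test = manifest$test,
                all = c(manifest$train, manifest$test))
  lapply(ids, function(id) {
    row <- tab[tab$image_id == id, ]
    if (nrow(row) != 1L) stop("image ", id, " missing from label table",
                              call. = FALSE)
    list(image = read_image(file.path(dir, "images", id)),
         mask = round(read_image(file.path(dir, "masks", id))),
         caption = row$caption,
         image_id = id)
  })
}
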
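# Squeeze-and-Excitation channel attention.
#
# A feature map U of shape (C, H, W) is pooled to a per-channel descriptor z
# (squeeze), passed through a two-layer bottleneck perceptron with a sigmoid
# (excite) to give per-channel weights s in (0,1), and each channel of U is
# rescaled by its weight (recalibrate). No bias terms on the two fully
# connected layers.
#
# All operations accept either plain numeric arrays or autodiff tensors
# (`vtensor`); with tensor inputs they stay on the tape, so the block is
# differentiable end-to-end inside the model.

.check_fmap <- function(u, what = "feature map") {
  v <- vt_value(u)
  d <- dim(v)
  if (is.null(d) || length(d) != 3L) {
    stop(what, " must be a (C, H, W) array", call. = FALSE)
  }
  if (any(d < 1L)) stop(what, " has an empty dimension", call. = FALSE)
  if (!all(is.finite(v))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(d)
}

# return numeric when every input was numeric, keep the tape otherwise
.maybe_value <- function(out, ...) {
  if (any(vapply(list(...), is_vt, logical(1)))) out else vt_value(out)
}

#' Squeeze-and-Excitation parameters
#'
#' Creates the two bottleneck weight matrices for an SE block acting on
#' `channels` feature channels. The hidden width is
#' `max(1, floor(channels / reduction_ratio))`; weights use a fan-in scaled
#' uniform initialization drawn from the current RNG state, so results are
#' reproducible under `set.seed()`.
#'
#' @param channels number of input channels C.
#' @param reduction_ratio bottleneck reduction ratio r (default 16, the
#'   original SE convention).
#' @return an object of class `se_params` with elements `w1` (hidden x C),
#'   `w2` (C x hidden) and `reduction_ratio`.
#' @export
#' @examples
#' set.seed(1)
#' p <- se_params(8, reduction_ratio = 2)
#' dim(p$w1)
se_params <- function(channels, reduction_ratio = 16) {
  stopifnot(channels >= 1, reduction_ratio >= 1)
  hidden <- max(1L, channels %/% reduction_ratio)
  structure(
    list(w1 = matrix(init_uniform(c(hidden, channels), channels),
                     hidden, channels),
         w2 = matrix(init_uniform(c(channels, hidden), hidden),
                     channels, hidden),
         reduction_ratio = reduction_ratio),
    class = "se_params")
}

#' Squeeze: global average pooling per channel
#'
#' Computes the per-channel global descriptor `z_c`, the arithmetic mean of
#' channel `c` over all spatial positions.
#'
#' @param u a (C, H, W) numeric array or `vtensor`.
#' @return a length-C vector (or tensor) of channel descriptors.
#' @export
squeeze <- function(u) {
  .check_fmap(u)
  out <- v_global_avgpool(as_vt(u))
  .maybe_value(out, u)
}

#' Excite: bottleneck perceptron with sigmoid
#'
#' Maps a channel descriptor `z` to excitation weights
#' `s = sigmoid(W2 %*% relu(W1 %*% z))`, each strictly in (0, 1).
#'
#' @param z length-C channel descriptor (vector or tensor).
#' @param p an [se_params()] object with `W1` of shape (hidden, C).
#' @return length-C excitation weights in (0, 1).
#' @export
excite <- function(z, p) {
  vz <- vt_value(z)
  if (length(vz) != ncol(vt_value(p$w1))) {
    stop("descriptor length ", length(vz), " does not match se_params for ",
         ncol(vt_value(p$w1)), " channels", call. = FALSE)
  }
  zt <- as_vt(z)
  h <- v_relu(v_matmul(as_vt(p$w1), v_matmul_vec(zt)))
  s <- v_sigmoid(v_matmul(as_vt(p$w2), h))
  out <- v_drop_dim(s)
  .maybe_value(out, z, p$w1, p$w2)
}

# column-vector view of a length-n tensor, and its inverse
v_matmul_vec <- function(x) {
  x <- as_vt(x)
  n <- length(x$value)
  vt(matrix(x$value, n, 1L), list(x), function(g) list(as.vector(g)))
}

v_drop_dim <- function(x) {
  x <- as_vt(x)
  vt(as.vector(x$value), list(x),
     function(g) list(matrix(g, length(g), 1L)))
}

#' Recalibrate: rescale channels by excitation weights
#'
#' @param u a (C, H, W) feature map.
#' @param s length-C excitation weights.
#' @return feature map of the same shape with channel `c` multiplied by `s_c`.
#' @export
recalibrate <- function(u, s) {
  d <- .check_fmap(u)
  if (length(vt_value(s)) != d[1L]) {
    stop("excitation length ", length(vt_value(s)),
         " does not match channel count ", d[1L], call. = FALSE)
  }
  out <- v_scale_channels(as_vt(u), as_vt(s))
  .maybe_value(out, u, s)
}

#' Full Squeeze-and-Excitation block
#'
#' `recalibrate(u, excite(squeeze(u), p))`. Differentiable end-to-end when
#' called with tensors.
#'
#' @inheritParams recalibrate
#' @param p an [se_params()] object.
#' @export
#' @examples
#' set.seed(1)
#' u <- array(rnorm(4 * 6 * 6), c(4, 6, 6))
#' p <- se_params(4, reduction_ratio = 2)
#' out <- se_block(u, p)
#' stopifnot(all(abs(out) <= abs(u)))   # weights are in (0,1)
se_block <- function(u, p) {
  recalibrate(u, excite(squeeze(u), p))
}
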
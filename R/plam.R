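# Pixel-Level Attention Module (PLAM), applied at CNN-branch skip
# connections to preserve local features.
#
# Wiring (committed, CBAM-style sequential channel-then-spatial):
#   1. channel attention: global-average and global-max descriptors are each
#      passed through a shared two-layer perceptron, summed, sigmoid-squashed
#      and used to rescale channels;
#   2. spatial attention: the per-pixel channel mean and channel max maps are
#      stacked as a 2-channel image and convolved (7x7, padding 3) to a
#      sigmoid map rescaling positions of the channel-attended map;
#   3. merge: a 1x1 convolution of the attended map is residual-added to the
#      input, so zero merge weights reduce the module exactly to identity.

#' PLAM parameters
#'
#' @param channels number of channels C of the skip connection.
#' @param reduction_ratio bottleneck ratio of the shared channel perceptron.
#' @param spatial_kernel odd kernel size of the spatial-attention convolution.
#' @param merge_zero_init logical; initialize the 1x1 merge projection at
#'   zero so the module starts as identity (default TRUE).
#' @return an object of class `plam_params`.
#' @export
plam_params <- function(channels, reduction_ratio = 8, spatial_kernel = 7,
                        merge_zero_init = TRUE) {
  stopifnot(channels >= 1, spatial_kernel %% 2 == 1)
  hidden <- max(1L, channels %/% reduction_ratio)
  structure(
    list(mlp_w1 = matrix(init_uniform(c(hidden, channels), channels),
                         hidden, channels),
         mlp_w2 = matrix(init_uniform(c(channels, hidden), hidden),
                         channels, hidden),
         spatial = init_conv(1L, 2L, spatial_kernel),
         merge = init_conv(channels, channels, 1L, zero = merge_zero_init),
         spatial_kernel = spatial_kernel),
    class = "plam_params")
}

# per-pixel mean/max over channels, stacked as a (2, H, W) map
v_spatial_stats <- function(u) {
  u <- as_vt(u)
  v <- u$value
  d <- dim(v)
  m <- matrix(v, d[1L])
  mean_map <- colMeans(m)
  jmax <- max.col(t(m), ties.method = "first")
  max_map <- m[cbind(jmax, seq_len(d[2L] * d[3L]))]
  out <- array(0, c(2L, d[2L], d[3L]))
  out[1L, , ] <- mean_map
  out[2L, , ] <- max_map
  vt(out, list(u), function(g) {
    gm <- matrix(g[1L, , ], 1L)
    gx <- matrix(g[2L, , ], 1L)
    dm <- matrix(rep(gm / d[1L], each = d[1L]), d[1L])
    dm[cbind(jmax, seq_len(ncol(dm)))] <-
      dm[cbind(jmax, seq_len(ncol(dm)))] + as.vector(gx)
    list(array(dm, d))
  })
}

#' Apply the pixel-level attention module
#'
#' Channel attention (shared perceptron over GAP and GMP descriptors),
#' followed by spatial attention (7x7 convolution of stacked mean/max maps),
#' followed by a 1x1 merge projection residual-added to the input. Output has
#' the same shape as the input. Accepts plain arrays or autodiff tensors.
#'
#' @param skip a (C, H, W) feature map (array or `vtensor`).
#' @param p a [plam_params()] object (its arrays may be `vtensor`s).
#' @return attended feature map, same shape as `skip`.
#' @export
plam_apply <- function(skip, p) {
  d <- .check_fmap(skip, "skip connection")
  if (ncol(vt_value(p$mlp_w1)) != d[1L]) {
    stop("plam_params configured for ", ncol(vt_value(p$mlp_w1)),
         " channels, got ", d[1L], call. = FALSE)
  }
  u <- as_vt(skip)
  w1 <- as_vt(p$mlp_w1); w2 <- as_vt(p$mlp_w2)
  # channel attention: shared MLP over GAP and GMP descriptors
  mlp <- function(z) v_matmul(w2, v_relu(v_matmul(w1, v_matmul_vec(z))))
  ch_logit <- v_add(mlp(v_global_avgpool(u)), mlp(v_global_maxpool(u)))
  ch_gate <- v_sigmoid(v_drop_dim(ch_logit))
  att <- v_scale_channels(u, ch_gate)
  # spatial attention on the channel-attended map
  pad <- (p$spatial_kernel - 1L) %/% 2L
  sp_logit <- v_conv2d(v_spatial_stats(att), as_vt(p$spatial$w),
                       as_vt(p$spatial$b), pad = pad)
  sp_gate <- v_sigmoid(v_reshape_mat(sp_logit, d[2L], d[3L]))
  att <- v_scale_spatial(att, sp_gate)
  # merge projection + residual
  out <- v_add(v_conv2d(att, as_vt(p$merge$w), as_vt(p$merge$b), pad = 0L), u)
  .maybe_value(out, skip, p$mlp_w1)
}

# (1, H, W) -> (H, W) matrix view
v_reshape_mat <- function(x, h, w) {
  x <- as_vt(x)
  vt(matrix(x$value[1L, , ], h, w), list(x),
     function(g) list(array(g, c(1L, h, w))))
}
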
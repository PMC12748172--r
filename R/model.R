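# Assembly of the dual-branch image-text segmentation model.
#
# CNN branch: U-shaped encoder/decoder with double-convolution stages,
# optional SE blocks (placement: none / down / up / all), PLAM at every skip
# connection, and a 1-channel segmentation head. Transformer branch: image
# tokens from the bottleneck feature map, fused with the projected pooled
# text embedding, run through a U-shaped stack of (optionally gated)
# transformer layers; its output map re-enters the decoder by
# concatenation followed by a 1x1 projection.

#' Model configuration
#'
#' @param se_placement `"none"`, `"down"` (after each encoder stage's
#'   convolutions), `"up"` (after each decoder stage), or `"all"`.
#' @param gating_enabled use gated residual connections in the transformer
#'   branch; `se_placement = "none"` plus `gating_enabled = FALSE` is the
#'   baseline model with exactly zero SE/gate parameters.
#' @param base_channels channels of the first encoder stage (doubles per
#'   stage). 64 at paper scale; 8 in the CPU test profile.
#' @param depth number of encoder/decoder stages (downsampling factor
#'   2^depth).
#' @param vit_dim transformer token dimension D.
#' @param vit_heads attention heads (must divide `vit_dim`).
#' @param vit_depth gated layers per U level per direction.
#' @param vit_levels token scales in the transformer branch.
#' @param text_embedder `"stub"` or `"pretrained"` (see [embed_text()]).
#' @param input_size integer c(H, W); must be divisible by
#'   `2^depth * 2^(vit_levels - 1)`.
#' @param se_reduction SE bottleneck ratio r.
#' @param gate_granularity 1 (scalar gate per token) or `vit_dim`.
#' @param text_dim text embedding dimension fed to the fusion projection.
#' @return object of class `model_config`.
#' @export
model_config <- function(se_placement = c("none", "down", "up", "all"),
                         gating_enabled = TRUE,
                         base_channels = 8L,
                         depth = 3L,
                         vit_dim = 32L,
                         vit_heads = 4L,
                         vit_depth = 1L,
                         vit_levels = 2L,
                         text_embedder = c("stub", "pretrained"),
                         input_size = c(64L, 64L),
                         se_reduction = 16L,
                         gate_granularity = 1L,
                         text_dim = 768L) {
  se_placement <- match.arg(se_placement)
  text_embedder <- match.arg(text_embedder)
  input_size <- as.integer(input_size)
  down_factor <- 2L^depth * 2L^(vit_levels - 1L)
  if (any(input_size %% down_factor != 0L)) {
    stop("input_size must be divisible by ", down_factor,
         " (2^depth * 2^(vit_levels-1))", call. = FALSE)
  }
  if (vit_dim %% vit_heads != 0L) {
    stop("vit_heads must divide vit_dim", call. = FALSE)
  }
  structure(list(se_placement = se_placement,
                 gating_enabled = gating_enabled,
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 vit_dim = as.integer(vit_dim),
                 vit_heads = as.integer(vit_heads),
                 vit_depth = as.integer(vit_depth),
                 vit_levels = as.integer(vit_levels),
                 text_embedder = text_embedder,
                 input_size = input_size,
                 se_reduction = as.integer(se_reduction),
                 gate_granularity = as.integer(gate_granularity),
                 text_dim = as.integer(text_dim)),
            class = "model_config")
}

# channel width of encoder stage i (1-based)
.stage_channels <- function(cfg, i) cfg$base_channels * 2L^(i - 1L)

#' Build the model
#'
#' Creates all parameters (seedable via `set.seed()` before the call, or the
#' `seed` argument) and returns a model object whose nested parameter list
#' mirrors the architecture.
#'
#' @param cfg a [model_config()].
#' @param seed optional integer seed for weight initialization.
#' @return object of class `vv_model`: list(cfg, params).
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  dpt <- cfg$depth
  se_down <- cfg$se_placement %in% c("down", "all")
  se_up <- cfg$se_placement %in% c("up", "all")
  mk_se <- function(ch) {
    p <- se_params(ch, cfg$se_reduction)
    list(w1 = p$w1, w2 = p$w2)
  }
  enc <- vector("list", dpt)
  c_prev <- 1L
  for (i in seq_len(dpt)) {
    ci <- .stage_channels(cfg, i)
    enc[[i]] <- list(conv1 = init_conv(ci, c_prev, 3L),
                     conv2 = init_conv(ci, ci, 3L),
                     plam = unclass(plam_params(ci)))
    if (se_down) enc[[i]]$se <- mk_se(ci)
    c_prev <- ci
  }
  c_bott <- cfg$base_channels * 2L^dpt
  bott <- list(conv1 = init_conv(c_bott, c_prev, 3L),
               conv2 = init_conv(c_bott, c_bott, 3L))
  vit <- list(token_proj = init_linear(cfg$vit_dim, c_bott),
              branch = unclass(vit_params(cfg$vit_dim, cfg$text_dim,
                                          cfg$vit_levels, cfg$vit_depth,
                                          cfg$vit_heads,
                                          cfg$gate_granularity,
                                          cfg$gating_enabled)),
              out_proj = init_linear(c_bott, cfg$vit_dim))
  vit$branch$down <- lapply(vit$branch$down, function(lv) lapply(lv, unclass))
  vit$branch$up <- lapply(vit$branch$up, function(lv) lapply(lv, unclass))
  fuse <- init_conv(c_bott, 2L * c_bott, 1L)
  dec <- vector("list", dpt)
  ch_in <- c_bott
  for (i in rev(seq_len(dpt))) {
    ci <- .stage_channels(cfg, i)
    dec[[i]] <- list(upconv = init_conv(ci, ch_in, 3L),
                     conv1 = init_conv(ci, 2L * ci, 3L),
                     conv2 = init_conv(ci, ci, 3L))
    if (se_up) dec[[i]]$se <- mk_se(ci)
    ch_in <- ci
  }
  head <- init_conv(1L, cfg$base_channels, 1L)
  structure(list(cfg = cfg,
                 params = list(enc = enc, bott = bott, vit = vit,
                               fuse = fuse, dec = dec, head = head)),
            class = "vv_model")
}

#' @export
print.vv_model <- function(x, ...) {
  cat(sprintf(
    "<vv_model: depth %d, base %d, SE %s, gating %s, vit D=%d L=%d, %d params>\n",
    x$cfg$depth, x$cfg$base_channels, x$cfg$se_placement,
    x$cfg$gating_enabled, x$cfg$vit_dim, x$cfg$vit_levels,
    n_params(x$params)))
  invisible(x)
}

#' Number of trainable parameters
#' @param model a `vv_model`.
#' @export
model_n_params <- function(model) n_params(model$params)

# double convolution with relu, optional SE block
.enc_stage <- function(x, p) {
  x <- v_relu(v_conv2d(x, p$conv1$w, p$conv1$b, pad = 1L))
  x <- v_relu(v_conv2d(x, p$conv2$w, p$conv2$b, pad = 1L))
  if (!is.null(p$se)) x <- se_block(x, p$se)
  x
}

#' Forward pass
#'
#' @param model a `vv_model` (numeric parameters) or a wrapped model whose
#'   parameters are autodiff tensors (as used internally by [train()]).
#' @param image (H, W) matrix matching `cfg$input_size`, values in [0, 1]
#'   (preprocessed).
#' @param text_emb (T, text_dim) text token embedding matrix, or NULL to run
#'   without text.
#' @return list(logits, prob): (H, W) matrices (or tensors when the model is
#'   wrapped).
#' @export
forward_model <- function(model, image, text_emb = NULL) {
  cfg <- model$cfg
  mp <- model$params
  h <- cfg$input_size[1L]; w <- cfg$input_size[2L]
  iv <- vt_value(image)
  if (!is.matrix(iv) || nrow(iv) != h || ncol(iv) != w) {
    stop("image must be a ", h, "x", w, " matrix", call. = FALSE)
  }
  x <- vt(array(iv, c(1L, h, w)))
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    x <- .enc_stage(x, mp$enc[[i]])
    skips[[i]] <- plam_apply(x, structure(
      c(mp$enc[[i]]$plam, list()), class = "plam_params"))
    x <- v_maxpool2(x)
  }
  x <- v_relu(v_conv2d(x, mp$bott$conv1$w, mp$bott$conv1$b, pad = 1L))
  xb <- v_relu(v_conv2d(x, mp$bott$conv2$w, mp$bott$conv2$b, pad = 1L))
  hb <- h %/% 2L^cfg$depth; wb <- w %/% 2L^cfg$depth
  tokens <- v_linear(v_tokens_from_map(xb),
                     mp$vit$token_proj$w, mp$vit$token_proj$b)
  branch <- structure(mp$vit$branch, class = "vit_params")
  vb <- vit_branch(tokens, text_emb, branch, grid = c(hb, wb))
  vit_map <- v_map_from_tokens(
    v_linear(vb$final, mp$vit$out_proj$w, mp$vit$out_proj$b), hb, wb)
  x <- v_relu(v_conv2d(v_concat_channels(xb, vit_map),
                       mp$fuse$w, mp$fuse$b, pad = 0L))
  for (i in rev(seq_len(cfg$depth))) {
    p <- mp$dec[[i]]
    x <- v_relu(v_conv2d(v_upsample2(x), p$upconv$w, p$upconv$b, pad = 1L))
    x <- v_concat_channels(x, skips[[i]])
    x <- v_relu(v_conv2d(x, p$conv1$w, p$conv1$b, pad = 1L))
    x <- v_relu(v_conv2d(x, p$conv2$w, p$conv2$b, pad = 1L))
    if (!is.null(p$se)) x <- se_block(x, p$se)
  }
  logits <- v_conv2d(x, mp$head$w, mp$head$b, pad = 0L)
  logits <- v_reshape_mat(logits, h, w)
  wrapped <- is_vt(mp$head$w)
  if (wrapped) {
    list(logits = logits, prob = v_sigmoid(logits))
  } else {
    list(logits = vt_value(logits),
         prob = stats::plogis(vt_value(logits)))
  }
}

#' Predict a probability map for one image
#'
#' @param model a `vv_model`.
#' @param image (H, W) matrix in [0, 1].
#' @param caption optional caption string; embedded with the configured text
#'   embedder. Empty or NULL runs the model without text.
#' @param seed stub-embedder seed.
#' @return (H, W) matrix of vessel probabilities in (0, 1).
#' @export
predict_mask <- function(model, image, caption = NULL, seed = 0L) {
  emb <- if (is.null(caption) || !nzchar(caption)) NULL else
    embed_text(caption, model$cfg$text_embedder,
               d_text = model$cfg$text_dim, seed = seed)
  forward_model(model, image, emb)$prob
}
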
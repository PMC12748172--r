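# Transformer layers with gated residual connections, and the U-shaped
# transformer branch fusing image tokens with a text embedding.
#
# Gated residual learning replaces both residual connections of a standard
# transformer layer by
#     y' = Gate_attn(x)  * Attn(x)   + x
#     y  = Gate_mlp(y')  * MLP(y')   + y'
# where each gate is the sigmoid of a learned affine map of the sub-layer
# input (one scalar per token by default, optionally one value per feature).
# Pre-normalization: layer norm is applied to the sub-layer input before
# Attn/MLP; the gate multiplies the sub-layer output before the residual add.

#' Gate parameters for one transformer layer
#'
#' @param d token embedding dimension D.
#' @param granularity 1 for one scalar gate per token (default), or `d` for a
#'   per-feature gate.
#' @param bias_init initial gate bias; 0 starts every gate at 0.5.
#' @return object of class `gate_params` with `attn_w`, `attn_b`, `mlp_w`,
#'   `mlp_b`, `granularity`. Weights start at zero so the initial gate is
#'   spatially uniform.
#' @export
gate_params <- function(d, granularity = 1L, bias_init = 0) {
  if (!granularity %in% c(1L, d)) {
    stop("granularity must be 1 or d = ", d, call. = FALSE)
  }
  g <- as.integer(granularity)
  structure(
    list(attn_w = matrix(0, g, d), attn_b = rep(bias_init, g),
         mlp_w = matrix(0, g, d), mlp_b = rep(bias_init, g),
         granularity = g),
    class = "gate_params")
}

#' Per-token gate values
#'
#' Sigmoid of the selected affine map applied per token; every entry lies
#' strictly in (0, 1).
#'
#' @param x token matrix (N, D) (array or `vtensor`).
#' @param g a [gate_params()] object.
#' @param which `"attn"` or `"mlp"`: which gate to evaluate.
#' @return (N, granularity) matrix of gate values in (0, 1).
#' @export
gate_signal <- function(x, g, which = c("attn", "mlp")) {
  which <- match.arg(which)
  vx <- vt_value(x)
  if (!is.matrix(vx)) stop("tokens must be an (N, D) matrix", call. = FALSE)
  w <- if (which == "attn") g$attn_w else g$mlp_w
  b <- if (which == "attn") g$attn_b else g$mlp_b
  if (ncol(vt_value(w)) != ncol(vx)) {
    stop("gate configured for D = ", ncol(vt_value(w)),
         ", tokens have D = ", ncol(vx), call. = FALSE)
  }
  out <- v_sigmoid(v_linear(as_vt(x), as_vt(w), as_vt(b)))
  .maybe_value(out, x, w)
}

#' Parameters of one gated transformer layer
#'
#' Multi-head self-attention (h heads, head dim D/h), a feed-forward block
#' D -> 4D -> D, two pre-layer-norms, and a [gate_params()] pair.
#'
#' @param d token dimension D.
#' @param heads number of attention heads; must divide `d`.
#' @param gate_granularity passed to [gate_params()].
#' @return object of class `transformer_layer_params`.
#' @export
transformer_layer_params <- function(d, heads = 4L, gate_granularity = 1L) {
  if (d %% heads != 0L) stop("heads must divide d", call. = FALSE)
  structure(
    list(wq = init_linear(d, d), wk = init_linear(d, d),
         wv = init_linear(d, d), wo = init_linear(d, d),
         ff1 = init_linear(4L * d, d), ff2 = init_linear(d, 4L * d),
         ln1_g = rep(1, d), ln1_b = numeric(d),
         ln2_g = rep(1, d), ln2_b = numeric(d),
         gate = gate_params(d, gate_granularity),
         heads = as.integer(heads), d = as.integer(d)),
    class = "transformer_layer_params")
}

# multi-head self-attention on (N, D) tokens; softmax rows sum to one
v_mha <- function(x, p) {
  d <- p$d; h <- p$heads; dh <- d %/% h
  q <- v_linear(x, as_vt(p$wq$w), as_vt(p$wq$b))
  k <- v_linear(x, as_vt(p$wk$w), as_vt(p$wk$b))
  v <- v_linear(x, as_vt(p$wv$w), as_vt(p$wv$b))
  heads_out <- vector("list", h)
  for (i in seq_len(h)) {
    idx <- (i - 1L) * dh + seq_len(dh)
    qi <- v_slice_cols(q, idx); ki <- v_slice_cols(k, idx)
    vi <- v_slice_cols(v, idx)
    scores <- v_mul(v_matmul(qi, v_transpose(ki)), 1 / sqrt(dh))
    heads_out[[i]] <- v_matmul(v_softmax_rows(scores), vi)
  }
  v_linear(v_concat_cols(heads_out), as_vt(p$wo$w), as_vt(p$wo$b))
}

v_transpose <- function(x) {
  x <- as_vt(x)
  vt(t(x$value), list(x), function(g) list(t(g)))
}

# attention matrices of every head (values only), for invariant checks
attention_rows <- function(x, p) {
  x <- vt_value(x)
  d <- p$d; h <- p$heads; dh <- d %/% h
  ln <- vt_value(v_layernorm(v_const(x), vt_value(p$ln1_g), vt_value(p$ln1_b)))
  q <- ln %*% t(vt_value(p$wq$w)) + rep(1, nrow(ln)) %o% vt_value(p$wq$b)
  k <- ln %*% t(vt_value(p$wk$w)) + rep(1, nrow(ln)) %o% vt_value(p$wk$b)
  lapply(seq_len(h), function(i) {
    idx <- (i - 1L) * dh + seq_len(dh)
    sc <- q[, idx, drop = FALSE] %*% t(k[, idx, drop = FALSE]) / sqrt(dh)
    vt_value(v_softmax_rows(v_const(sc)))
  })
}

#' One gated transformer layer
#'
#' Pre-norm multi-head self-attention and feed-forward blocks, each entering
#' the residual stream through a learned sigmoid gate computed from the
#' sub-layer input. Shape (N, D) is preserved.
#'
#' @param x (N, D) token matrix (array or `vtensor`).
#' @param p a [transformer_layer_params()] object.
#' @return token matrix of the same shape.
#' @export
gated_layer <- function(x, p) {
  vx <- vt_value(x)
  if (!is.matrix(vx) || ncol(vx) != p$d) {
    stop("tokens must be (N, ", p$d, ")", call. = FALSE)
  }
  xt <- as_vt(x)
  a <- v_mha(v_layernorm(xt, as_vt(p$ln1_g), as_vt(p$ln1_b)), p)
  g_attn <- v_sigmoid(v_linear(xt, as_vt(p$gate$attn_w), as_vt(p$gate$attn_b)))
  y1 <- v_add(v_rowscale(a, g_attn), xt)
  mlp_in <- v_layernorm(y1, as_vt(p$ln2_g), as_vt(p$ln2_b))
  m <- v_linear(v_relu(v_linear(mlp_in, as_vt(p$ff1$w), as_vt(p$ff1$b))),
                as_vt(p$ff2$w), as_vt(p$ff2$b))
  g_mlp <- v_sigmoid(v_linear(y1, as_vt(p$gate$mlp_w), as_vt(p$gate$mlp_b)))
  out <- v_add(v_rowscale(m, g_mlp), y1)
  .maybe_value(out, x, p$wq$w)
}

#' Parameters of the U-shaped transformer branch
#'
#' `levels` is the number of token scales; level 1 is the input grid, and
#' tokens are 2x2 average-merged between levels. Each level carries
#' `depth_per_level` gated layers on the way down and (for levels above the
#' bottom) on the way up. A pooled text embedding of dimension `d_text` is
#' projected to D and added to every image token at branch entry (zero text
#' leaves the branch untouched because the projection bias starts at zero).
#'
#' @param d token dimension D.
#' @param d_text text embedding dimension (768 for BERT-base conventions).
#' @param levels number of U levels (>= 1).
#' @param depth_per_level gated layers per level per direction.
#' @param heads attention heads per layer.
#' @param gate_granularity passed to [gate_params()].
#' @param gating_enabled if FALSE no gate parameters are created and plain
#'   residual connections are used (the baseline transformer branch).
#' @return object of class `vit_params`.
#' @export
vit_params <- function(d, d_text = 768L, levels = 2L, depth_per_level = 1L,
                       heads = 4L, gate_granularity = 1L,
                       gating_enabled = TRUE) {
  mk_layer <- function() {
    p <- transformer_layer_params(d, heads, gate_granularity)
    if (!gating_enabled) p$gate <- NULL
    p
  }
  mk_level <- function() lapply(seq_len(depth_per_level), function(i) mk_layer())
  structure(
    list(text_proj = init_linear(d, d_text, zero = TRUE),
         down = lapply(seq_len(levels), function(l) mk_level()),
         up = if (levels > 1L)
           lapply(seq_len(levels - 1L), function(l) mk_level()) else list(),
         d = as.integer(d), levels = as.integer(levels),
         gating_enabled = gating_enabled),
    class = "vit_params")
}

# plain (ungated) pre-norm transformer layer; used when gating is disabled
ungated_layer <- function(x, p) {
  xt <- as_vt(x)
  a <- v_mha(v_layernorm(xt, as_vt(p$ln1_g), as_vt(p$ln1_b)), p)
  y1 <- v_add(a, xt)
  mlp_in <- v_layernorm(y1, as_vt(p$ln2_g), as_vt(p$ln2_b))
  m <- v_linear(v_relu(v_linear(mlp_in, as_vt(p$ff1$w), as_vt(p$ff1$b))),
                as_vt(p$ff2$w), as_vt(p$ff2$b))
  v_add(m, y1)
}

apply_layer <- function(x, p) {
  if (is.null(p$gate)) ungated_layer(x, p) else gated_layer(x, p)
}

#' U-shaped gated transformer branch with text fusion
#'
#' Image tokens (N = grid_h * grid_w rows) are fused with the mean-pooled
#' text embedding (projected to D, broadcast-added to every token), then run
#' through gated layers at each U level with 2x2 token merging on the way
#' down and nearest-neighbour unmerging plus skip addition on the way up.
#'
#' @param image_tokens (N, D) matrix or `vtensor`.
#' @param text_tokens (T, d_text) matrix of text token embeddings, or NULL
#'   for no text.
#' @param p a [vit_params()] object.
#' @param grid integer c(grid_h, grid_w) with `grid_h * grid_w == N`.
#' @return list with `per_level` (token outputs at each level, coarsest
#'   first) and `final` (tokens at the input grid resolution).
#' @export
vit_branch <- function(image_tokens, text_tokens, p, grid) {
  vx <- vt_value(image_tokens)
  stopifnot(is.matrix(vx), length(grid) == 2L)
  if (nrow(vx) != grid[1L] * grid[2L]) {
    stop("token count ", nrow(vx), " does not match grid ",
         grid[1L], "x", grid[2L], call. = FALSE)
  }
  if (ncol(vx) != p$d) stop("token dimension must be ", p$d, call. = FALSE)
  x <- as_vt(image_tokens)
  if (!is.null(text_tokens)) {
    ttv <- vt_value(text_tokens)
    if (ncol(ttv) != ncol(vt_value(p$text_proj$w))) {
      stop("text embedding dimension ", ncol(ttv), " does not match branch (",
           ncol(vt_value(p$text_proj$w)), ")", call. = FALSE)
    }
    pooled <- matrix(colMeans(ttv), 1L)
    txt <- v_linear(v_const(pooled), as_vt(p$text_proj$w),
                    as_vt(p$text_proj$b))
    x <- v_add_rowvec(x, txt)
  }
  hs <- integer(p$levels); ws <- integer(p$levels)
  hs[1L] <- grid[1L]; ws[1L] <- grid[2L]
  skips <- vector("list", p$levels)
  for (l in seq_len(p$levels)) {
    for (layer in p$down[[l]]) x <- apply_layer(x, layer)
    skips[[l]] <- x
    if (l < p$levels) {
      if (hs[l] %% 2L != 0L || ws[l] %% 2L != 0L) {
        stop("token grid not divisible by 2 at level ", l, call. = FALSE)
      }
      x <- v_token_merge2(x, hs[l], ws[l])
      hs[l + 1L] <- hs[l] %/% 2L
      ws[l + 1L] <- ws[l] %/% 2L
    }
  }
  per_level <- list(x)  # bottom level output
  if (p$levels > 1L) {
    for (l in rev(seq_len(p$levels - 1L))) {
      x <- v_token_unmerge2(x, hs[l], ws[l])
      x <- v_add(x, skips[[l]])
      for (layer in p$up[[l]]) x <- apply_layer(x, layer)
      per_level <- c(per_level, list(x))
    }
  }
  keep_tensor <- is_vt(image_tokens) || is_vt(p$text_proj$w)
  if (!keep_tensor) per_level <- lapply(per_level, vt_value)
  list(per_level = per_level,
       final = per_level[[length(per_level)]])
}

# broadcast-add a (1, D) row vector to every row of x
v_add_rowvec <- function(x, r) {
  x <- as_vt(x); r <- as_vt(r)
  vt(sweep(x$value, 2L, as.vector(r$value), "+"), list(x, r), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}
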
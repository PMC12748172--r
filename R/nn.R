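# Parameter initialization and the Adam optimizer.

# Fan-in scaled uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in)); seedable
# through the caller's RNG state.
init_uniform <- function(dims, fan_in) {
  stopifnot(fan_in >= 1)
  lim <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

init_linear <- function(d_out, d_in, bias = TRUE, zero = FALSE) {
  w <- if (zero) matrix(0, d_out, d_in) else
    matrix(init_uniform(c(d_out, d_in), d_in), d_out, d_in)
  out <- list(w = w)
  if (bias) out$b <- numeric(d_out)
  out
}

init_conv <- function(c_out, c_in, k, zero = FALSE) {
  fan_in <- c_in * k * k
  w <- if (zero) array(0, c(c_out, c_in, k, k)) else
    init_uniform(c(c_out, c_in, k, k), fan_in)
  list(w = w, b = numeric(c_out))
}

# Structural metadata fields that live inside parameter objects but are not
# trainable (never wrapped, never counted).
.meta_fields <- c("reduction_ratio", "spatial_kernel", "granularity",
                  "heads", "d", "levels", "gating_enabled")

# Recursively wrap the numeric arrays of a nested parameter list into
# v_param tensors, preserving structure, classes and metadata fields.
wrap_params <- function(x) {
  if (is_vt(x)) return(x)
  if (is.numeric(x)) return(v_param(x))
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.null(nms) && nms[i] %in% .meta_fields) next
      x[[i]] <- wrap_params(x[[i]])
    }
    return(x)
  }
  x
}

unwrap_params <- function(x) {
  if (is_vt(x)) return(x$value)
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      if (!is.null(nms) && nms[i] %in% .meta_fields) next
      x[[i]] <- unwrap_params(x[[i]])
    }
    return(x)
  }
  x
}

# Flatten a nested parameter list to a named flat list (names joined by "."),
# skipping metadata fields.
flatten_params <- function(x, prefix = NULL) {
  if (is_vt(x) || is.numeric(x)) {
    out <- list(x)
    names(out) <- prefix
    return(out)
  }
  if (!is.list(x)) return(list())
  nms <- names(x)
  if (is.null(nms)) nms <- as.character(seq_along(x))
  out <- list()
  for (i in seq_along(x)) {
    if (nms[i] %in% .meta_fields) next
    nm <- if (is.null(prefix)) nms[i] else paste(prefix, nms[i], sep = ".")
    out <- c(out, flatten_params(x[[i]], nm))
  }
  out
}

n_params <- function(x) {
  sum(vapply(flatten_params(x), function(p) length(vt_value(p)), numeric(1)))
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params_flat, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params_flat, function(p) vt_value(p) * 0),
       v = lapply(params_flat, function(p) vt_value(p) * 0))
}

# params_flat: flat list of v_param tensors with accumulated $grad.
# Mutates tensor values in place; clears gradients.
adam_step <- function(opt, params_flat) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(params_flat)) {
    p <- params_flat[[i]]
    g <- p$grad
    if (is.null(g)) next
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    p$value <- p$value -
      opt$lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + opt$eps)
    p$grad <- NULL
  }
  opt
}

zero_grads <- function(params_flat) {
  for (p in params_flat) p$grad <- NULL
  invisible(params_flat)
}
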
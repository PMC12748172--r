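# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Tensors are environments carrying a value, a list of parent tensors and a
# backward closure mapping the output gradient to per-parent gradients.
# Gradients are only propagated through nodes that (transitively) depend on a
# parameter, so constant subgraphs cost nothing on the backward pass.
#
# Feature maps use channel-first (C, H, W) layout; token matrices are (N, D).

.vv_state <- new.env(parent = emptyenv())
.vv_state$id <- 0

#' Create an autodiff tensor
#'
#' @param value numeric vector, matrix or array.
#' @param parents list of parent `vtensor`s this node was computed from.
#' @param backward function(grad) returning a list of gradients, one per
#'   parent (NULL entries allowed for parents that need no gradient).
#' @param requires_grad logical; mark this node as a trainable leaf.
#' @return a `vtensor`.
#' @keywords internal
vt <- function(value, parents = list(), backward = NULL, requires_grad = FALSE) {
  stopifnot(is.numeric(value))
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad
  e$needs <- requires_grad ||
    any(vapply(parents, function(p) p$needs, logical(1)))
  e$grad <- NULL
  .vv_state$id <- .vv_state$id + 1
  e$id <- .vv_state$id
  class(e) <- "vtensor"
  e
}

#' @export
print.vtensor <- function(x, ...) {
  d <- dim(x$value)
  cat("<vtensor", if (is.null(d)) sprintf("len %d", length(x$value))
      else paste(d, collapse = "x"),
      if (x$requires_grad) "param" else "", ">\n")
  invisible(x)
}

v_param <- function(value) vt(value, requires_grad = TRUE)
v_const <- function(value) vt(value)
is_vt <- function(x) inherits(x, "vtensor")
as_vt <- function(x) if (is_vt(x)) x else vt(x)
vt_value <- function(x) if (is_vt(x)) x$value else x

# Topologically sort the graph under `root` and accumulate gradients into the
# `grad` field of every node with `needs = TRUE`. Seeds with d(root)/d(root)=1.
vt_backward <- function(root) {
  stopifnot(is_vt(root))
  topo <- vector("list", 256L)
  n_topo <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  # iterative DFS (graphs can be deep for stacked transformer layers)
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 1L) {
      if (!is.null(visited[[key]])) next
      assign(key, TRUE, envir = visited)
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        if (p$needs && is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_topo <- n_topo + 1L
      if (n_topo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[n_topo]] <- nd
    }
  }
  topo <- topo[seq_len(n_topo)]
  for (nd in topo) nd$grad <- NULL
  root$grad <- if (is.null(dim(root$value))) rep(1, length(root$value)) else
    array(1, dim = dim(root$value))
  for (i in rev(seq_len(n_topo))) {
    nd <- topo[[i]]
    if (is.null(nd$backward) || is.null(nd$grad)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$needs || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(root)
}

# ---- elementwise and scalar ops ---------------------------------------------

# collapse a gradient to a scalar when the operand was length-1 (broadcast)
.vv_reduce <- function(g, v) if (length(v) == 1L) sum(g) else g

.vv_check_ew <- function(a, b) {
  if (length(a) != length(b) && length(a) != 1L && length(b) != 1L) {
    stop("elementwise op on incompatible shapes (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
}

v_add <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  .vv_check_ew(a$value, b$value)
  va <- a$value; vb <- b$value
  vt(va + vb, list(a, b),
     function(g) list(.vv_reduce(g, va), .vv_reduce(g, vb)))
}

v_sub <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  .vv_check_ew(a$value, b$value)
  va <- a$value; vb <- b$value
  vt(va - vb, list(a, b),
     function(g) list(.vv_reduce(g, va), .vv_reduce(-g, vb)))
}

v_mul <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  .vv_check_ew(a$value, b$value)
  va <- a$value; vb <- b$value
  vt(va * vb, list(a, b),
     function(g) list(.vv_reduce(g * vb, va), .vv_reduce(g * va, vb)))
}

v_div <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  .vv_check_ew(a$value, b$value)
  va <- a$value; vb <- b$value
  vt(va / vb, list(a, b),
     function(g) list(.vv_reduce(g / vb, va),
                      .vv_reduce(-g * va / (vb * vb), vb)))
}

v_relu <- function(x) {
  x <- as_vt(x)
  v <- x$value
  out <- v
  out[out < 0] <- 0
  vt(out, list(x), function(g) list(g * (v > 0)))
}

v_sigmoid <- function(x) {
  x <- as_vt(x)
  s <- stats::plogis(x$value)
  vt(s, list(x), function(g) list(g * s * (1 - s)))
}

v_sum <- function(x) {
  x <- as_vt(x)
  vt(sum(x$value), list(x), function(g) {
    list(if (is.null(dim(x$value))) rep(g, length(x$value))
         else array(g, dim = dim(x$value)))
  })
}

v_mean <- function(x) {
  x <- as_vt(x)
  n <- length(x$value)
  vt(mean(x$value), list(x), function(g) {
    list(if (is.null(dim(x$value))) rep(g / n, n)
         else array(g / n, dim = dim(x$value)))
  })
}

# ---- linear algebra ---------------------------------------------------------

v_matmul <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  va <- a$value; vb <- b$value
  vt(va %*% vb, list(a, b),
     function(g) list(g %*% t(vb), t(va) %*% g))
}

# x: (N, D_in); w: (D_out, D_in); b: length D_out. Returns (N, D_out).
v_linear <- function(x, w, b = NULL) {
  x <- as_vt(x); w <- as_vt(w)
  vx <- x$value; vw <- w$value
  out <- vx %*% t(vw)
  if (is.null(b)) {
    return(vt(out, list(x, w),
              function(g) list(g %*% vw, t(g) %*% vx)))
  }
  b <- as_vt(b)
  out <- sweep(out, 2L, b$value, "+")
  vt(out, list(x, w, b),
     function(g) list(g %*% vw, t(g) %*% vx, colSums(g)))
}

v_slice_cols <- function(x, idx) {
  x <- as_vt(x)
  vx <- x$value
  vt(vx[, idx, drop = FALSE], list(x), function(g) {
    z <- matrix(0, nrow(vx), ncol(vx))
    z[, idx] <- g
    list(z)
  })
}

v_concat_cols <- function(lst) {
  lst <- lapply(lst, as_vt)
  widths <- vapply(lst, function(t) ncol(t$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  vt(do.call(cbind, lapply(lst, `[[`, "value")), lst, function(g) {
    lapply(seq_along(lst), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

v_softmax_rows <- function(x) {
  x <- as_vt(x)
  v <- x$value
  m <- apply(v, 1L, max)
  e <- exp(v - m)
  s <- e / rowSums(e)
  vt(s, list(x), function(g) {
    list(s * (g - rowSums(g * s)))
  })
}

# Per-token (row-wise) layer normalization with learnable gain/offset.
v_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_vt(x); gamma <- as_vt(gamma); beta <- as_vt(beta)
  v <- x$value
  d <- ncol(v)
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  vt(out, list(x, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, gamma$value, "*")
    dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
    list(dx, colSums(g * xhat), colSums(g))
  })
}

# Scale every row i of x (N, D) by s[i] (s is (N,1)) or elementwise ((N,D)).
v_rowscale <- function(x, s) {
  x <- as_vt(x); s <- as_vt(s)
  vx <- x$value; vs <- s$value
  per_token <- ncol(vs) == 1L
  out <- if (per_token) vx * as.vector(vs) else vx * vs
  vt(out, list(x, s), function(g) {
    if (per_token) {
      list(g * as.vector(vs), matrix(rowSums(g * vx), ncol = 1L))
    } else {
      list(g * vs, g * vx)
    }
  })
}

# ---- feature-map (C, H, W) ops ----------------------------------------------

.vv_dims3 <- function(v) {
  d <- dim(v)
  if (is.null(d) || length(d) != 3L) {
    stop("expected a (C, H, W) array", call. = FALSE)
  }
  d
}

# 2-D convolution via im2col, stride 1, zero padding `pad`.
# x (Cin,H,W), w (Cout,Cin,k,k), b length Cout.
v_conv2d <- function(x, w, b = NULL, pad = 1L) {
  x <- as_vt(x); w <- as_vt(w)
  vx <- x$value
  vw <- w$value
  d <- .vv_dims3(vx)
  cin <- d[1L]; h <- d[2L]; wd <- d[3L]
  k <- dim(vw)[3L]
  stopifnot(dim(vw)[2L] == cin, dim(vw)[4L] == k)
  cout <- dim(vw)[1L]
  hp <- h + 2L * pad; wp <- wd + 2L * pad
  xp <- array(0, c(cin, hp, wp))
  xp[, pad + seq_len(h), pad + seq_len(wd)] <- vx
  # columns ordered channel-fastest, then kernel col offset, then row offset
  m <- matrix(0, h * wd, cin * k * k)
  blk <- 0L
  for (di in 0:(k - 1L)) {
    for (dj in 0:(k - 1L)) {
      sub <- xp[, di + seq_len(h), dj + seq_len(wd), drop = FALSE]
      m[, blk * cin + seq_len(cin)] <- matrix(aperm(sub, c(2L, 3L, 1L)),
                                              h * wd, cin)
      blk <- blk + 1L
    }
  }
  # flatten weights to (Cout, Cin*k*k) matching the column order above
  wm <- matrix(aperm(vw, c(2L, 4L, 3L, 1L)), cin * k * k, cout)
  out_mat <- m %*% wm
  parents <- list(x, w)
  if (!is.null(b)) {
    b <- as_vt(b)
    out_mat <- sweep(out_mat, 2L, b$value, "+")
    parents <- list(x, w, b)
  }
  out <- aperm(array(out_mat, c(h, wd, cout)), c(3L, 1L, 2L))
  vt(out, parents, function(g) {
    g_mat <- matrix(aperm(g, c(2L, 3L, 1L)), h * wd, cout)
    dwm <- crossprod(m, g_mat)                      # (Cin*k*k, Cout)
    dw <- aperm(array(dwm, c(cin, k, k, cout)), c(4L, 1L, 3L, 2L))
    dm <- g_mat %*% t(wm)                           # (H*W, Cin*k*k)
    dxp <- array(0, c(cin, hp, wp))
    blk <- 0L
    for (di in 0:(k - 1L)) {
      for (dj in 0:(k - 1L)) {
        piece <- aperm(array(dm[, blk * cin + seq_len(cin)], c(h, wd, cin)),
                       c(3L, 1L, 2L))
        dxp[, di + seq_len(h), dj + seq_len(wd)] <-
          dxp[, di + seq_len(h), dj + seq_len(wd), drop = FALSE] + piece
        blk <- blk + 1L
      }
    }
    dx <- dxp[, pad + seq_len(h), pad + seq_len(wd), drop = FALSE]
    if (is.null(b)) list(dx, dw) else list(dx, dw, colSums(g_mat))
  })
}

v_maxpool2 <- function(x) {
  x <- as_vt(x)
  v <- x$value
  d <- .vv_dims3(v)
  cch <- d[1L]; h <- d[2L]; wd <- d[3L]
  stopifnot(h %% 2L == 0L, wd %% 2L == 0L)
  oi <- seq(1L, h, 2L); ei <- oi + 1L
  oj <- seq(1L, wd, 2L); ej <- oj + 1L
  cand <- list(v[, oi, oj, drop = FALSE], v[, ei, oj, drop = FALSE],
               v[, oi, ej, drop = FALSE], v[, ei, ej, drop = FALSE])
  cur <- cand[[1L]]
  idx <- array(1L, dim(cur))
  for (kk in 2:4) {
    upd <- cand[[kk]] > cur
    idx[upd] <- kk
    cur[upd] <- cand[[kk]][upd]
  }
  vt(cur, list(x), function(g) {
    dx <- array(0, d)
    sel_rows <- list(oi, ei, oi, ei)
    sel_cols <- list(oj, oj, ej, ej)
    for (kk in 1:4) {
      gz <- g
      gz[idx != kk] <- 0
      dx[, sel_rows[[kk]], sel_cols[[kk]]] <-
        dx[, sel_rows[[kk]], sel_cols[[kk]], drop = FALSE] + gz
    }
    list(dx)
  })
}

# Nearest-neighbour 2x upsampling.
v_upsample2 <- function(x) {
  x <- as_vt(x)
  v <- x$value
  d <- .vv_dims3(v)
  ri <- rep(seq_len(d[2L]), each = 2L)
  rj <- rep(seq_len(d[3L]), each = 2L)
  vt(v[, ri, rj, drop = FALSE], list(x), function(g) {
    oi <- seq(1L, 2L * d[2L], 2L)
    oj <- seq(1L, 2L * d[3L], 2L)
    g2 <- g[, oi, , drop = FALSE] + g[, oi + 1L, , drop = FALSE]
    list(g2[, , oj, drop = FALSE] + g2[, , oj + 1L, drop = FALSE])
  })
}

v_concat_channels <- function(a, b) {
  a <- as_vt(a); b <- as_vt(b)
  da <- .vv_dims3(a$value); db <- .vv_dims3(b$value)
  stopifnot(da[2L] == db[2L], da[3L] == db[3L])
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L]))
  out[seq_len(da[1L]), , ] <- a$value
  out[da[1L] + seq_len(db[1L]), , ] <- b$value
  vt(out, list(a, b), function(g) {
    list(g[seq_len(da[1L]), , , drop = FALSE],
         g[da[1L] + seq_len(db[1L]), , , drop = FALSE])
  })
}

v_global_avgpool <- function(x) {
  x <- as_vt(x)
  d <- .vv_dims3(x$value)
  n_sp <- d[2L] * d[3L]
  vt(rowMeans(matrix(x$value, d[1L])), list(x),
     function(g) list(array(g / n_sp, d)))
}

v_global_maxpool <- function(x) {
  x <- as_vt(x)
  d <- .vv_dims3(x$value)
  m <- matrix(x$value, d[1L])
  jmax <- max.col(m, ties.method = "first")
  vals <- m[cbind(seq_len(d[1L]), jmax)]
  vt(vals, list(x), function(g) {
    z <- matrix(0, d[1L], d[2L] * d[3L])
    z[cbind(seq_len(d[1L]), jmax)] <- g
    list(array(z, d))
  })
}

# Scale channel c of u (C,H,W) by s[c] (length C).
v_scale_channels <- function(u, s) {
  u <- as_vt(u); s <- as_vt(s)
  d <- .vv_dims3(u$value)
  stopifnot(length(s$value) == d[1L])
  vu <- u$value; vs <- as.vector(s$value)
  vt(vu * vs, list(u, s), function(g) {
    list(g * vs, rowSums(matrix(g * vu, d[1L])))
  })
}

# Scale position (h,w) of u (C,H,W) by m[h,w] (H,W matrix).
v_scale_spatial <- function(u, m) {
  u <- as_vt(u); m <- as_vt(m)
  d <- .vv_dims3(u$value)
  stopifnot(all(dim(m$value) == d[2:3]))
  vu <- u$value
  mm <- rep(as.vector(m$value), each = d[1L])
  vt(vu * mm, list(u, m), function(g) {
    list(g * mm, matrix(colSums(matrix(g * vu, d[1L])), d[2L], d[3L]))
  })
}

# (C,H,W) feature map -> (H*W, C) token matrix; row index runs h fastest.
v_tokens_from_map <- function(u) {
  u <- as_vt(u)
  d <- .vv_dims3(u$value)
  vt(t(matrix(u$value, d[1L])), list(u),
     function(g) list(array(t(g), d)))
}

# (N, C) tokens on an (H, W) grid -> (C, H, W) feature map.
v_map_from_tokens <- function(tk, h, w) {
  tk <- as_vt(tk)
  v <- tk$value
  stopifnot(nrow(v) == h * w)
  vt(array(t(v), c(ncol(v), h, w)), list(tk),
     function(g) list(t(matrix(g, ncol(v)))))
}

# Average 2x2 neighbourhoods of tokens living on an (h, w) grid.
v_token_merge2 <- function(tk, h, w) {
  tk <- as_vt(tk)
  v <- tk$value
  d <- ncol(v)
  stopifnot(nrow(v) == h * w, h %% 2L == 0L, w %% 2L == 0L)
  a <- array(v, c(h, w, d))
  oi <- seq(1L, h, 2L); oj <- seq(1L, w, 2L)
  avg <- (a[oi, oj, , drop = FALSE] + a[oi + 1L, oj, , drop = FALSE] +
          a[oi, oj + 1L, , drop = FALSE] + a[oi + 1L, oj + 1L, , drop = FALSE]) / 4
  vt(matrix(avg, (h / 2L) * (w / 2L), d), list(tk), function(g) {
    ga <- array(g, c(h / 2L, w / 2L, d)) / 4
    ri <- rep(seq_len(h / 2L), each = 2L)
    rj <- rep(seq_len(w / 2L), each = 2L)
    list(matrix(ga[ri, rj, , drop = FALSE], h * w, d))
  })
}

# Nearest-neighbour unmerge back to an (h, w) grid (inputs live on h/2 x w/2).
v_token_unmerge2 <- function(tk, h, w) {
  tk <- as_vt(tk)
  v <- tk$value
  d <- ncol(v)
  stopifnot(nrow(v) == (h / 2L) * (w / 2L))
  a <- array(v, c(h / 2L, w / 2L, d))
  ri <- rep(seq_len(h / 2L), each = 2L)
  rj <- rep(seq_len(w / 2L), each = 2L)
  vt(matrix(a[ri, rj, , drop = FALSE], h * w, d), list(tk), function(g) {
    ga <- array(g, c(h, w, d))
    oi <- seq(1L, h, 2L); oj <- seq(1L, w, 2L)
    s <- ga[oi, oj, , drop = FALSE] + ga[oi + 1L, oj, , drop = FALSE] +
      ga[oi, oj + 1L, , drop = FALSE] + ga[oi + 1L, oj + 1L, , drop = FALSE]
    list(matrix(s, (h / 2L) * (w / 2L), d))
  })
}

# ---- losses -----------------------------------------------------------------

# Numerically stable mean binary cross-entropy on logits; y is a constant
# target in {0,1} (or soft labels in [0,1]).
v_bce_with_logits <- function(z, y) {
  z <- as_vt(z)
  y <- vt_value(y)
  vz <- z$value
  n <- length(vz)
  val <- mean(pmax(vz, 0) - vz * y + log1p(exp(-abs(vz))))
  vt(val, list(z), function(g) {
    list(g * (stats::plogis(vz) - y) / n)
  })
}

# Soft Dice loss on probabilities: 1 - (2*sum(p*y)+eps) / (sum(p)+sum(y)+eps).
v_dice_loss <- function(p, y, eps = 1) {
  p <- as_vt(p)
  yc <- v_const(vt_value(y))
  num <- v_add(v_mul(v_sum(v_mul(p, yc)), 2), eps)
  den <- v_add(v_add(v_sum(p), v_sum(yc)), eps)
  v_sub(1, v_div(num, den))
}
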
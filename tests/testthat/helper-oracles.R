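# Independent loop-level reference implementations. Deliberately naive
# (nested loops, no vectorization, no code shared with R/) so they can serve
# as oracles for the package's implementations.

oracle_squeeze <- function(u) {
  d <- dim(u)
  z <- numeric(d[1])
  for (c in seq_len(d[1])) {
    acc <- 0
    for (i in seq_len(d[2])) for (j in seq_len(d[3])) acc <- acc + u[c, i, j]
    z[c] <- acc / (d[2] * d[3])
  }
  z
}

oracle_excite <- function(z, w1, w2) {
  hid <- numeric(nrow(w1))
  for (r in seq_len(nrow(w1))) {
    acc <- 0
    for (c in seq_along(z)) acc <- acc + w1[r, c] * z[c]
    hid[r] <- max(acc, 0)
  }
  s <- numeric(nrow(w2))
  for (r in seq_len(nrow(w2))) {
    acc <- 0
    for (c in seq_along(hid)) acc <- acc + w2[r, c] * hid[c]
    s[r] <- 1 / (1 + exp(-acc))
  }
  s
}

oracle_se_block <- function(u, w1, w2) {
  s <- oracle_excite(oracle_squeeze(u), w1, w2)
  out <- u
  for (c in seq_len(dim(u)[1])) out[c, , ] <- s[c] * u[c, , ]
  out
}

oracle_confusion <- function(pred, gt) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1
    else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1
    else if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1
    else fn <- fn + 1
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_metrics <- function(cc) {
  list(f1 = 2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn),
       acc = (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn),
       se = cc$tp / (cc$tp + cc$fn),
       sp = cc$tn / (cc$tn + cc$fp))
}

oracle_gate <- function(x, w, b) {
  n <- nrow(x); g <- nrow(w)
  out <- matrix(0, n, g)
  for (i in seq_len(n)) for (r in seq_len(g)) {
    acc <- b[r]
    for (c in seq_len(ncol(x))) acc <- acc + w[r, c] * x[i, c]
    out[i, r] <- 1 / (1 + exp(-acc))
  }
  out
}

oracle_affine <- function(x, w, b) {
  n <- nrow(x)
  out <- matrix(0, n, nrow(w))
  for (i in seq_len(n)) for (r in seq_len(nrow(w))) {
    acc <- b[r]
    for (c in seq_len(ncol(x))) acc <- acc + w[r, c] * x[i, c]
    out[i, r] <- acc
  }
  out
}

oracle_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    va <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(va + eps) * gamma + beta
  }
  out
}

oracle_mha <- function(x, p) {
  d <- p$d; h <- p$heads; dh <- d / h
  q <- oracle_affine(x, p$wq$w, p$wq$b)
  k <- oracle_affine(x, p$wk$w, p$wk$b)
  v <- oracle_affine(x, p$wv$w, p$wv$b)
  n <- nrow(x)
  concat <- matrix(0, n, d)
  for (head in seq_len(h)) {
    idx <- (head - 1) * dh + seq_len(dh)
    for (i in seq_len(n)) {
      scores <- numeric(n)
      for (j in seq_len(n)) {
        scores[j] <- sum(q[i, idx] * k[j, idx]) / sqrt(dh)
      }
      w_att <- exp(scores - max(scores))
      w_att <- w_att / sum(w_att)
      for (j in seq_len(n)) {
        concat[i, idx] <- concat[i, idx] + w_att[j] * v[j, idx]
      }
    }
  }
  oracle_affine(concat, p$wo$w, p$wo$b)
}

# full pre-norm gated transformer layer, wired exactly as declared
oracle_gated_layer <- function(x, p) {
  a <- oracle_mha(oracle_layernorm(x, p$ln1_g, p$ln1_b), p)
  g_attn <- oracle_gate(x, p$gate$attn_w, p$gate$attn_b)
  y1 <- x
  for (i in seq_len(nrow(x))) y1[i, ] <- g_attn[i, 1] * a[i, ] + x[i, ]
  hmat <- oracle_affine(oracle_layernorm(y1, p$ln2_g, p$ln2_b),
                        p$ff1$w, p$ff1$b)
  hmat[hmat < 0] <- 0
  m <- oracle_affine(hmat, p$ff2$w, p$ff2$b)
  g_mlp <- oracle_gate(y1, p$gate$mlp_w, p$gate$mlp_b)
  y <- y1
  for (i in seq_len(nrow(x))) y[i, ] <- g_mlp[i, 1] * m[i, ] + y1[i, ]
  y
}

# step-by-step PLAM wiring: channel attention (shared MLP over GAP/GMP),
# spatial attention (7x7 conv of stacked mean/max maps), merge 1x1 conv +
# residual
oracle_plam <- function(u, p) {
  d <- dim(u)
  gap <- oracle_squeeze(u)
  gmp <- numeric(d[1])
  for (c in seq_len(d[1])) gmp[c] <- max(u[c, , ])
  mlp <- function(z) {
    hid <- pmax(as.vector(p$mlp_w1 %*% z), 0)
    as.vector(p$mlp_w2 %*% hid)
  }
  ch <- 1 / (1 + exp(-(mlp(gap) + mlp(gmp))))
  att <- u
  for (c in seq_len(d[1])) att[c, , ] <- ch[c] * u[c, , ]
  mean_map <- apply(att, c(2, 3), mean)
  max_map <- apply(att, c(2, 3), max)
  k <- p$spatial_kernel
  pad <- (k - 1) / 2
  sp <- matrix(0, d[2], d[3])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) {
    acc <- p$spatial$b[1]
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + ki - 1 - pad; jj <- j + kj - 1 - pad
      if (ii >= 1 && ii <= d[2] && jj >= 1 && jj <= d[3]) {
        acc <- acc + p$spatial$w[1, 1, ki, kj] * mean_map[ii, jj] +
          p$spatial$w[1, 2, ki, kj] * max_map[ii, jj]
      }
    }
    sp[i, j] <- 1 / (1 + exp(-acc))
  }
  for (c in seq_len(d[1])) att[c, , ] <- att[c, , ] * sp
  merged <- u * 0
  for (co in seq_len(d[1])) {
    acc <- matrix(p$merge$b[co], d[2], d[3])
    for (ci in seq_len(d[1])) {
      acc <- acc + p$merge$w[co, ci, 1, 1] * att[ci, , ]
    }
    merged[co, , ] <- acc
  }
  merged + u
}

# clipped-histogram equalization on a 2x1 vertical tiling, loop level
oracle_clahe_2x1 <- function(img, clip_limit, nbins = 256) {
  h <- nrow(img); w <- ncol(img)
  bin <- pmin(floor(img * nbins) + 1, nbins)
  half <- floor(h / 2)
  tiles <- list(1:half, (half + 1):h)
  cdfs <- list()
  centres <- numeric(2)
  for (t in 1:2) {
    rows <- tiles[[t]]
    hist <- numeric(nbins)
    for (i in rows) for (j in seq_len(w)) {
      hist[bin[i, j]] <- hist[bin[i, j]] + 1
    }
    n <- length(rows) * w
    clip <- max(clip_limit * n / nbins, 1)
    excess <- sum(pmax(hist - clip, 0))
    hist <- pmin(hist, clip) + excess / nbins
    cdfs[[t]] <- cumsum(hist) / n
    centres[t] <- mean(range(rows))
  }
  out <- img
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (i <= centres[1]) {
      out[i, j] <- cdfs[[1]][bin[i, j]]
    } else if (i >= centres[2]) {
      out[i, j] <- cdfs[[2]][bin[i, j]]
    } else {
      f <- (i - centres[1]) / (centres[2] - centres[1])
      out[i, j] <- (1 - f) * cdfs[[1]][bin[i, j]] + f * cdfs[[2]][bin[i, j]]
    }
  }
  out
}

# small helpers for building random test fixtures
rand_fmap <- function(c, h, w) array(stats::rnorm(c * h * w), c(c, h, w))
rand_mask <- function(h, w, p = 0.3) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
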
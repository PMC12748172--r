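# Finite-difference validation of the reverse-mode engine: every composite
# block used by the model is checked against central differences.

fd_check <- function(make_loss, param, idx, tol = 1e-4) {
  im <- rbind(idx)    # matrix-style index into the array
  param$grad <- NULL
  loss <- make_loss()
  vt_backward(loss)
  g_an <- param$grad[im]
  param$grad <- NULL
  eps <- 1e-6
  v0 <- param$value
  param$value[im] <- v0[im] + eps
  up <- vt_value(make_loss())
  param$value[im] <- v0[im] - eps
  dn <- vt_value(make_loss())
  param$value <- v0
  expect_equal((up - dn) / (2 * eps), g_an, tolerance = tol)
}

test_that("conv/pool/upsample/concat gradients match finite differences", {
  set.seed(61)
  x <- rand_fmap(2, 8, 8)
  p <- wrap_params(list(c1 = init_conv(3, 2, 3), c2 = init_conv(2, 5, 1)))
  make_loss <- function() {
    h <- v_relu(v_conv2d(vt(x), p$c1$w, p$c1$b, pad = 1L))
    h <- v_maxpool2(h)
    h <- v_upsample2(h)
    h <- v_concat_channels(h, vt(x))
    h <- v_conv2d(h, p$c2$w, p$c2$b, pad = 0L)
    v_mean(v_mul(h, h))
  }
  fd_check(make_loss, p$c1$w, c(2, 1, 3, 1))
  fd_check(make_loss, p$c1$b, 2)
  fd_check(make_loss, p$c2$w, c(1, 4, 1, 1))
})

test_that("token reshaping, merging and scaling gradients are exact", {
  set.seed(62)
  u <- rand_fmap(3, 4, 4)
  p <- wrap_params(list(w = matrix(rnorm(3 * 3), 3, 3) * 0.3,
                        s = runif(3), m = matrix(runif(16), 4, 4)))
  make_loss <- function() {
    h <- v_scale_channels(vt(u), p$s)
    h <- v_scale_spatial(h, p$m)
    tk <- v_tokens_from_map(h)
    tk <- v_matmul(tk, p$w)
    tk <- v_token_merge2(tk, 4L, 4L)
    tk <- v_token_unmerge2(tk, 4L, 4L)
    h2 <- v_map_from_tokens(tk, 4L, 4L)
    v_sum(v_mul(h2, h2))
  }
  fd_check(make_loss, p$w, c(2, 3))
  fd_check(make_loss, p$s, 1)
  fd_check(make_loss, p$m, c(3, 2))
})

test_that("softmax, layernorm and losses back-propagate correctly", {
  set.seed(63)
  x <- matrix(rnorm(4 * 6), 4, 6)
  y <- matrix(as.numeric(runif(24) > 0.5), 4, 6)
  p <- wrap_params(list(w = matrix(rnorm(36) * 0.4, 6, 6),
                        g = runif(6, 0.5, 1.5), b = rnorm(6)))
  make_loss <- function() {
    h <- v_layernorm(v_matmul(vt(x), p$w), p$g, p$b)
    att <- v_softmax_rows(v_matmul(h, v_transpose(h)))
    h2 <- v_matmul(att, h)
    v_add(v_bce_with_logits(h2, y), v_dice_loss(v_sigmoid(h2), y))
  }
  fd_check(make_loss, p$w, c(3, 5))
  fd_check(make_loss, p$g, 2)
  fd_check(make_loss, p$b, 4)
})

test_that("global pooling ops route gradients to the right positions", {
  set.seed(64)
  u <- rand_fmap(3, 5, 5)
  p <- wrap_params(list(u = u))
  make_loss <- function() {
    v_sum(v_add(v_mul(v_global_avgpool(p$u), 2),
                v_mul(v_global_maxpool(p$u), 3)))
  }
  loss <- make_loss()
  vt_backward(loss)
  # avg contributes 2/25 everywhere; max adds 3 at each channel argmax
  g <- p$u$grad
  expect_equal(sum(abs(g - 2 / 25) > 1e-9), 3L)
  for (c in 1:3) {
    expect_equal(max(g[c, , ]), 2 / 25 + 3)
  }
  fd_check(make_loss, p$u, c(2, 4, 4))
})

test_that("whole-model gradients agree with finite differences", {
  set.seed(65)
  ds <- make_toy_dataset(1, seed = 66)
  m <- build_model(toy_model_config(se_placement = "all",
                                    gating_enabled = TRUE), seed = 7)
  wm <- m
  wm$params <- wrap_params(m$params)
  emb <- embed_text(ds[[1]]$caption, "stub", seed = 1)
  make_loss <- function() {
    out <- forward_model(wm, ds[[1]]$image, emb)
    vesselvit:::segmentation_loss(out$logits, ds[[1]]$mask + 0)
  }
  # touch one parameter from each architectural group
  fd_check(make_loss, wm$params$enc[[1]]$conv1$w, c(1, 1, 2, 2), tol = 1e-3)
  fd_check(make_loss, wm$params$enc[[2]]$se$w1, c(1, 3), tol = 1e-3)
  fd_check(make_loss, wm$params$vit$branch$down[[1]][[1]]$gate$attn_b, 1,
           tol = 1e-3)
  fd_check(make_loss, wm$params$vit$branch$text_proj$w, c(2, 10), tol = 1e-3)
  fd_check(make_loss, wm$params$dec[[1]]$conv2$w, c(2, 1, 1, 3), tol = 1e-3)
  fd_check(make_loss, wm$params$head$w, c(1, 2, 1, 1), tol = 1e-3)
})
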
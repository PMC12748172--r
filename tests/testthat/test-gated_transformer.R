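test_that("gate_signal is the per-token affine + sigmoid, entries in (0,1)", {
  set.seed(31)
  x <- matrix(rnorm(6 * 8), 6, 8)
  g0 <- gate_params(8)
  expect_equal(gate_signal(x, g0, "attn"), matrix(0.5, 6, 1))
  gneg <- gate_params(8, bias_init = -20)
  expect_true(all(gate_signal(x, gneg, "mlp") < 1e-8))
  g <- gate_params(8)
  g$attn_w <- matrix(rnorm(8), 1, 8)
  g$attn_b <- rnorm(1)
  expect_equal(gate_signal(x, g, "attn"),
               oracle_gate(x, g$attn_w, g$attn_b), tolerance = 1e-9)
  expect_error(gate_signal(matrix(0, 3, 4), g, "attn"), "configured for")
})

test_that("gate_signal matches the affine oracle on 100 random instances", {
  set.seed(32)
  for (rep_i in 1:100) {
    n <- sample(1:6, 1); d <- sample(c(4L, 8L), 1)
    x <- matrix(rnorm(n * d), n, d)
    g <- gate_params(d, granularity = sample(c(1L, d), 1))
    g$attn_w <- matrix(rnorm(length(g$attn_w)), nrow(g$attn_w), d)
    g$attn_b <- rnorm(length(g$attn_b))
    expect_equal(gate_signal(x, g, "attn"),
                 oracle_gate(x, g$attn_w, g$attn_b), tolerance = 1e-6)
  }
})

test_that("gate limits: 0 collapses the layer to identity, 1 to ungated", {
  set.seed(33)
  p <- transformer_layer_params(8, heads = 2)
  x <- matrix(rnorm(5 * 8), 5, 8)
  p0 <- p
  p0$gate$attn_b <- -Inf
  p0$gate$mlp_b <- -Inf
  expect_identical(gated_layer(x, p0), x)
  p1 <- p
  p1$gate$attn_b <- Inf
  p1$gate$mlp_b <- Inf
  expect_equal(gated_layer(x, p1),
               vt_value(vesselvit:::ungated_layer(x, p)), tolerance = 1e-12)
})

test_that("gates at 0.5 equal the half-residual composition of sub-blocks", {
  set.seed(34)
  p <- transformer_layer_params(8, heads = 2)   # zero gate weights: gate 0.5
  x <- matrix(rnorm(3 * 8), 3, 8)
  attn <- oracle_mha(oracle_layernorm(x, p$ln1_g, p$ln1_b), p)
  y1 <- 0.5 * attn + x
  h <- oracle_affine(oracle_layernorm(y1, p$ln2_g, p$ln2_b), p$ff1$w, p$ff1$b)
  h[h < 0] <- 0
  y <- 0.5 * oracle_affine(h, p$ff2$w, p$ff2$b) + y1
  expect_equal(gated_layer(x, p), y, tolerance = 1e-9)
})

test_that("gated_layer matches the full loop oracle on random instances", {
  set.seed(35)
  for (rep_i in 1:100) {
    n <- sample(2:5, 1)
    p <- transformer_layer_params(8, heads = sample(c(1L, 2L, 4L), 1))
    p$gate$attn_w <- matrix(rnorm(8), 1, 8)
    p$gate$mlp_w <- matrix(rnorm(8), 1, 8)
    p$gate$attn_b <- rnorm(1); p$gate$mlp_b <- rnorm(1)
    x <- matrix(rnorm(n * 8), n, 8)
    expect_equal(gated_layer(x, p), oracle_gated_layer(x, p),
                 tolerance = 1e-6)
  }
})

test_that("attention rows are nonnegative and sum to one on every head", {
  set.seed(36)
  p <- transformer_layer_params(12, heads = 3)
  x <- matrix(rnorm(7 * 12), 7, 12)
  for (a in vesselvit:::attention_rows(x, p)) {
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, 7), tolerance = 1e-9)
  }
})

test_that("vit_branch fuses text additively and conserves token counts", {
  set.seed(37)
  p <- vit_params(8, d_text = 16, levels = 2, depth_per_level = 1, heads = 2)
  tk <- matrix(rnorm(16 * 8), 16, 8)
  no_text <- vit_branch(tk, NULL, p, grid = c(4, 4))
  zero_text <- vit_branch(tk, matrix(0, 3, 16), p, grid = c(4, 4))
  expect_equal(no_text$final, zero_text$final, tolerance = 1e-12)
  expect_identical(nrow(no_text$final), 16L)
  expect_identical(nrow(no_text$per_level[[1]]), 4L)  # bottom level 2x2 grid
  expect_error(vit_branch(tk, matrix(0, 3, 9), p, grid = c(4, 4)),
               "dimension")
  expect_error(vit_branch(tk[1:15, ], NULL, p, grid = c(4, 4)), "grid")
})

test_that("depth-1 branch with gates at 0 passes image tokens through", {
  set.seed(38)
  p <- vit_params(8, d_text = 16, levels = 1, depth_per_level = 1, heads = 2)
  p$down[[1]][[1]]$gate$attn_b <- -Inf
  p$down[[1]][[1]]$gate$mlp_b <- -Inf
  tk <- matrix(rnorm(4 * 8), 4, 8)
  expect_identical(vit_branch(tk, NULL, p, grid = c(2, 2))$final, tk)
})

test_that("fixed config and seed give bitwise-reproducible branch outputs", {
  run_once <- function() {
    set.seed(39)
    p <- vit_params(32, d_text = 64, levels = 2, depth_per_level = 2,
                    heads = 4)
    tk <- matrix(rnorm(16 * 32), 16, 32)
    txt <- matrix(rnorm(5 * 64), 5, 64)
    vit_branch(tk, txt, p, grid = c(4, 4))$final
  }
  expect_identical(run_once(), run_once())
})
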
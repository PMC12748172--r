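test_that("squeeze matches the definition and the brute-force oracle", {
  expect_equal(squeeze(array(3, c(5, 4, 7))), rep(3, 5))
  expect_equal(squeeze(array(c(1, 3, 2, 4), c(1, 2, 2))), 2.5)
  set.seed(101)
  u <- rand_fmap(3, 4, 5)
  expect_equal(squeeze(u), oracle_squeeze(u), tolerance = 1e-9)
})

test_that("squeeze rejects malformed input", {
  expect_error(squeeze(matrix(1, 2, 2)), "C, H, W")
  expect_error(squeeze(array(c(1, NA, 1, 1), c(1, 2, 2))), "finite")
})

test_that("excite matches sigmoid(W2 relu(W1 z)) with entries in (0,1)", {
  p0 <- structure(list(w1 = matrix(0, 4, 8), w2 = matrix(0, 8, 4),
                       reduction_ratio = 2), class = "se_params")
  expect_equal(excite(rnorm(8), p0), rep(0.5, 8))
  # large positive weights on a positive descriptor saturate the sigmoid
  psat <- structure(list(w1 = matrix(10, 4, 8), w2 = matrix(10, 8, 4),
                         reduction_ratio = 2), class = "se_params")
  expect_true(all(excite(rep(1, 8), psat) > 0.999))
  set.seed(7)
  z <- rnorm(8)
  p <- se_params(8, reduction_ratio = 2)
  expect_equal(excite(z, p), oracle_excite(z, p$w1, p$w2), tolerance = 1e-9)
  expect_true(all(excite(z, p) > 0 & excite(z, p) < 1))
  expect_error(excite(rnorm(5), p), "does not match")
})

test_that("recalibrate scales channels and enforces shape agreement", {
  set.seed(8)
  u <- rand_fmap(3, 4, 4)
  expect_identical(recalibrate(u, rep(1, 3)), u)
  expect_equal(recalibrate(u, rep(0, 3)), u * 0)
  u1 <- rand_fmap(1, 5, 5)
  expect_equal(recalibrate(u1, 0.5), u1 / 2)
  expect_error(recalibrate(u, c(0.5, 0.5)), "does not match")
})

test_that("se_block composes the three steps and preserves shape", {
  set.seed(9)
  u <- rand_fmap(16, 32, 32)
  p <- se_params(16, reduction_ratio = 4)
  out <- se_block(u, p)
  expect_identical(dim(out), dim(u))
  # zero weights halve everything: excitation is sigmoid(0) = 0.5
  p0 <- structure(list(w1 = matrix(0, 4, 16), w2 = matrix(0, 16, 4),
                       reduction_ratio = 4), class = "se_params")
  expect_equal(se_block(u, p0), 0.5 * u, tolerance = 1e-12)
  # constant-per-channel input: output constant per channel, value z_c * s_c
  zc <- c(-1, 0.5, 2)
  uc <- array(rep(zc, 6 * 6), c(3, 6, 6))
  for (c in 1:3) uc[c, , ] <- zc[c]
  pc <- se_params(3, reduction_ratio = 1)
  s <- oracle_excite(zc, pc$w1, pc$w2)
  expect_equal(se_block(uc, pc)[, 2, 3], zc * s, tolerance = 1e-9)
})

test_that("se_block matches the loop oracle on many random instances", {
  set.seed(11)
  for (rep_i in 1:100) {
    cc <- sample(1:8, 1); h <- sample(1:8, 1); w <- sample(1:8, 1)
    u <- rand_fmap(cc, h, w)
    p <- se_params(cc, reduction_ratio = sample(c(1, 2, 4), 1))
    expect_equal(se_block(u, p), oracle_se_block(u, p$w1, p$w2),
                 tolerance = 1e-6)
  }
})

test_that("se_block output never exceeds input magnitude (s in (0,1))", {
  set.seed(12)
  for (rep_i in 1:20) {
    u <- rand_fmap(4, 6, 6)
    p <- se_params(4, reduction_ratio = 2)
    expect_true(all(abs(se_block(u, p)) <= abs(u) + 1e-12))
  }
})

test_that("consistent channel permutation permutes se_block output", {
  set.seed(13)
  u <- rand_fmap(6, 5, 5)
  p <- se_params(6, reduction_ratio = 2)
  perm <- sample(6)
  p_perm <- p
  p_perm$w1 <- p$w1[, perm]
  p_perm$w2 <- p$w2[perm, ]
  expect_equal(se_block(u[perm, , , drop = FALSE], p_perm),
               se_block(u, p)[perm, , , drop = FALSE], tolerance = 1e-12)
})

test_that("gradients flow through se_block to both weight matrices", {
  set.seed(14)
  u <- rand_fmap(4, 5, 5)
  p <- wrap_params(list(w1 = se_params(4, 2)$w1, w2 = se_params(4, 2)$w2))
  out <- se_block(vt(u), p)
  vt_backward(v_sum(v_mul(out, out)))
  expect_true(any(p$w1$grad != 0))
  expect_true(any(p$w2$grad != 0))
  # analytic gradient agrees with central finite differences
  f <- function() vt_value(v_sum(v_mul(se_block(vt(u), p), se_block(vt(u), p))))
  eps <- 1e-6
  g_an <- p$w1$grad[1, 2]
  w0 <- p$w1$value
  p$w1$value[1, 2] <- w0[1, 2] + eps; up <- f()
  p$w1$value[1, 2] <- w0[1, 2] - eps; dn <- f()
  p$w1$value <- w0
  expect_equal((up - dn) / (2 * eps), g_an, tolerance = 1e-4)
})
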
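test_that("forward pass honours the shape and range contract", {
  cfg <- toy_model_config(se_placement = "down", gating_enabled = TRUE)
  m <- build_model(cfg, seed = 1)
  ds <- make_toy_dataset(1, seed = 10)
  prob <- predict_mask(m, ds[[1]]$image, ds[[1]]$caption)
  expect_identical(dim(prob), c(32L, 32L))
  expect_true(all(prob > 0 & prob < 1))
  expect_error(forward_model(m, matrix(0, 16, 16)), "matrix")
  expect_error(model_config(input_size = c(60, 60)), "divisible")
})

test_that("parameter-count deltas match the closed-form SE/gate counts", {
  base <- toy_model_config(se_placement = "none", gating_enabled = FALSE)
  n_base <- model_n_params(build_model(base, seed = 1))
  for (pl in c("down", "up", "all")) {
    cfg <- toy_model_config(se_placement = pl, gating_enabled = FALSE)
    expect_equal(model_n_params(build_model(cfg, seed = 1)) - n_base,
                 se_param_count(cfg), info = pl)
  }
  cfg_g <- toy_model_config(se_placement = "none", gating_enabled = TRUE)
  expect_equal(model_n_params(build_model(cfg_g, seed = 1)) - n_base,
               gate_param_count(cfg_g))
  cfg_b <- toy_model_config(se_placement = "down", gating_enabled = TRUE)
  expect_equal(model_n_params(build_model(cfg_b, seed = 1)) - n_base,
               se_param_count(cfg_b) + gate_param_count(cfg_b))
})

test_that("baseline config carries exactly zero SE and gate parameters", {
  m <- build_model(toy_model_config(se_placement = "none",
                                    gating_enabled = FALSE), seed = 1)
  nms <- names(flatten_params(m$params))
  expect_false(any(grepl("\\.se\\.|gate", nms)))
})

test_that("zeroed SE weights halve the stage activation (all placements)", {
  cfg <- toy_model_config(se_placement = "all", gating_enabled = FALSE)
  m <- build_model(cfg, seed = 2)
  m0 <- build_model(toy_model_config(se_placement = "none",
                                     gating_enabled = FALSE), seed = 2)
  # same seed: the convolution weights of stage 1 coincide; zero the SE MLP
  m$params$enc[[1]]$se$w1[] <- 0
  m$params$enc[[1]]$se$w2[] <- 0
  img <- make_toy_dataset(1, seed = 3)[[1]]$image
  x <- vt(array(img, c(1L, 32L, 32L)))
  with_se <- vt_value(vesselvit:::.enc_stage(x, m$params$enc[[1]]))
  without <- vt_value(vesselvit:::.enc_stage(x, m0$params$enc[[1]]))
  expect_equal(with_se, 0.5 * without, tolerance = 1e-12)
})

test_that("one epoch on two samples yields a finite-loss checkpoint", {
  ds <- make_toy_dataset(2, seed = 20)
  m <- build_model(toy_model_config(), seed = 1)
  ck <- train(m, ds, train_config(epochs = 1, batch_size = 2, seed = 1))
  expect_s3_class(ck, "vv_checkpoint")
  expect_true(is.finite(ck$history$loss))
  expect_identical(dim(ck$data_order), c(1L, 2L))
})

test_that("zero learning rate leaves weights unchanged after an epoch", {
  ds <- make_toy_dataset(2, seed = 30)
  m <- build_model(toy_model_config(), seed = 1)
  ck <- train(m, ds, train_config(epochs = 1, learning_rate = 0, seed = 1))
  expect_identical(ck$params, m$params)
})

test_that("fixed-seed training reproduces the loss trajectory bitwise", {
  ds <- make_toy_dataset(2, seed = 40)
  run <- function() {
    m <- build_model(toy_model_config(), seed = 5)
    train(m, ds, train_config(epochs = 2, seed = 5))
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("checkpoint round-trip reproduces forward outputs bitwise", {
  ds <- make_toy_dataset(2, seed = 50)
  m <- build_model(toy_model_config(), seed = 1)
  ck <- train(m, ds, train_config(epochs = 1, seed = 1))
  path <- file.path(withr::local_tempdir(), "ck.rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  p1 <- forward_model(checkpoint_model(ck), ds[[1]]$image)$prob
  p2 <- forward_model(checkpoint_model(ck2), ds[[1]]$image)$prob
  expect_identical(p1, p2)
})

test_that("evaluate is deterministic, reports per-image, rejects empty", {
  ds <- make_toy_dataset(3, seed = 60)
  m <- build_model(toy_model_config(), seed = 1)
  ck <- train(m, ds[1:2], train_config(epochs = 1, seed = 1))
  r1 <- evaluate(ck, ds)
  r2 <- evaluate(ck, ds)
  expect_identical(unclass(r1)[c("f1", "acc", "se", "sp")],
                   unclass(r2)[c("f1", "acc", "se", "sp")])
  expect_identical(nrow(attr(r1, "per_image")), 3L)
  expect_error(evaluate(ck, list()), "empty dataset")
})

test_that("validation history and checkpoint-on-improvement work", {
  ds <- make_toy_dataset(3, seed = 75)
  m <- build_model(toy_model_config(), seed = 1)
  path <- file.path(withr::local_tempdir(), "best.rds")
  ck <- train(m, ds[1:2], train_config(epochs = 2, seed = 1),
              val_set = ds[3], checkpoint_path = path)
  expect_true(all(c("val_f1", "val_acc", "val_se", "val_sp") %in%
                    names(ck$history)))
  expect_true(file.exists(path))
  best <- load_checkpoint(path)
  expect_lte(best$epoch, 2L)
})

test_that("training runs with empty captions (text ablation hook)", {
  ds <- make_toy_dataset(2, seed = 70)
  for (i in seq_along(ds)) ds[[i]]$caption <- ""
  m <- build_model(toy_model_config(), seed = 1)
  ck <- train(m, ds, train_config(epochs = 1, seed = 1))
  rep <- evaluate(ck, ds)
  expect_true(all(unlist(unclass(rep)) >= 0 & unlist(unclass(rep)) <= 1,
                  na.rm = TRUE))
})

test_that("a tiny model memorizes two samples (overfit sanity oracle)", {
  ds <- make_toy_dataset(2, seed = 80)
  cfg <- model_config(se_placement = "down", gating_enabled = TRUE,
                      base_channels = 8L, depth = 2L, vit_dim = 16L,
                      vit_heads = 2L, vit_levels = 2L,
                      input_size = c(32L, 32L))
  m <- build_model(cfg, seed = 2)
  ck <- train(m, ds, train_config(epochs = 150, batch_size = 1,
                                  learning_rate = 0.003, seed = 2))
  rep <- evaluate(ck, ds)
  expect_lt(ck$history$loss[150], 0.5 * ck$history$loss[1])
  expect_gt(rep$f1, 0.95)
})

test_that("run_ablation emits one row per configuration with valid metrics", {
  ds <- make_toy_dataset(3, seed = 90)
  tcfg <- train_config(epochs = 1, seed = 1)
  tab <- run_ablation(c("none", "down"), TRUE, toy_model_config(), tcfg,
                      ds[1:2], ds[3])
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$se_placement, c("none", "down"))
  vals <- unlist(tab[, c("f1", "acc", "se", "sp")])
  expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
  orders <- attr(tab, "data_order")
  expect_identical(orders[[1]], orders[[2]])
  expect_error(run_ablation("none", TRUE, toy_model_config(), tcfg,
                            ds[1:2], ds[3]), "at least 2")
})
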
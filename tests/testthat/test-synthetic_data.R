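test_that("grow_vessel_tree honours depth, fovea and determinism contracts", {
  cfg0 <- synth_config("cf", depth = 0, n_trees = 5, seed = 3)
  set.seed(3)
  segs <- grow_vessel_tree(cfg0)
  expect_equal(nrow(segs), 5)          # depth 0: one trunk per seed point
  expect_true(all(segs$generation == 0))
  set.seed(3)
  expect_identical(grow_vessel_tree(cfg0), segs)
  expect_error(synth_config("octa", size = c(16, 16)), ">= 32")
  expect_error(synth_config("octa", width_decay = 1.2), "width_decay")
})

test_that("octa masks keep the central avascular disc empty across seeds", {
  for (seed in 1:20) {
    cfg <- synth_config("octa", fovea_radius_frac = 0.2, seed = seed)
    s <- generate_sample(cfg)
    h <- nrow(s$mask); w <- ncol(s$mask)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    r <- 0.2 * min(h, w) / 2
    py <- matrix(seq_len(h), h, w)
    px <- matrix(seq_len(w), h, w, byrow = TRUE)
    expect_equal(sum(s$mask[(py - cy)^2 + (px - cx)^2 < r^2]), 0)
  }
})

test_that("noiseless blur-free octa image is exactly the scaled mask", {
  cfg <- synth_config("octa", noise_sd = 0, blur_sigma = 0, p_abnormal = 0,
                      vessel_intensity = 0.85, seed = 4)
  s <- generate_sample(cfg)
  expect_equal(s$image, 0.85 * (s$mask + 0), tolerance = 1e-12)
})

test_that("density class always matches the class recomputed from the mask", {
  for (seed in c(1, 7, 19, 33, 55)) {
    for (mod in c("cf", "octa")) {
      cfg <- synth_config(mod, seed = seed)
      s <- generate_sample(cfg)
      expect_identical(s$label$density_class,
                       density_class_of(s$mask, cfg$density_cuts))
    }
  }
  # cut-point arithmetic, independent of the generator
  expect_identical(density_class_of(matrix(c(rep(1, 4), rep(0, 96)), 10),
                                    c(0.05, 0.15)), "sparse")
  expect_identical(density_class_of(matrix(c(rep(1, 10), rep(0, 90)), 10),
                                    c(0.05, 0.15)), "moderate")
  expect_identical(density_class_of(matrix(1, 4, 4), c(0.05, 0.15)), "dense")
})

test_that("vessel fraction stays inside the configured plausibility band", {
  for (mod in c("cf", "octa")) {
    fracs <- vapply(1:20, function(seed) {
      mean(generate_sample(synth_config(mod, seed = seed))$mask)
    }, numeric(1))
    band <- synth_config(mod)$density_band
    expect_true(all(fracs >= band[1] & fracs <= band[2]),
                info = sprintf("%s fractions: %s", mod,
                               paste(round(fracs, 3), collapse = " ")))
  }
})

test_that("different seeds give different masks", {
  a <- generate_sample(synth_config("octa", seed = 1))$mask
  b <- generate_sample(synth_config("octa", seed = 2))$mask
  expect_gt(sum(a != b), 0)
})

test_that("generate_dataset writes a consistent, reproducible corpus", {
  tmp <- withr::local_tempdir()
  cfg <- synth_config("octa", seed = 9)
  man <- generate_dataset(cfg, n_train = 20, n_test = 9,
                          out_dir = file.path(tmp, "d1"))
  expect_length(c(man$train, man$test), 29)
  expect_length(list.files(file.path(tmp, "d1", "images")), 29)
  expect_length(list.files(file.path(tmp, "d1", "masks")), 29)
  tab <- read_label_table(file.path(tmp, "d1", "labels.csv"))
  expect_setequal(tab$image_id, c(man$train, man$test))
  # byte-identical label tables on re-run with the same seed
  generate_dataset(cfg, n_train = 20, n_test = 9,
                   out_dir = file.path(tmp, "d2"))
  expect_identical(readBin(file.path(tmp, "d1", "labels.csv"), "raw", 1e6),
                   readBin(file.path(tmp, "d2", "labels.csv"), "raw", 1e6))
  id <- man$train[1]
  expect_identical(readBin(file.path(tmp, "d1", "images", id), "raw", 1e6),
                   readBin(file.path(tmp, "d2", "images", id), "raw", 1e6))
  # loader pairs images, masks and captions
  ds <- load_dataset(file.path(tmp, "d1"), "test")
  expect_length(ds, 9)
  expect_true(all(vapply(ds, function(s)
    all(dim(s$image) == cfg$size) && all(s$mask %in% c(0, 1)) &&
      nzchar(s$caption), logical(1))))
})
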
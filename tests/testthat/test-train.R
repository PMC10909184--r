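test_that("the training defaults carry the reference recipe", {
  tc <- lfc_training_config()
  expect_identical(tc$batch_size, 24L)
  expect_identical(tc$epochs, 2000L)
  expect_equal(tc$lr_initial, 1e-3)
  expect_identical(tc$lr_halving_period, 500L)
  expect_identical(tc$patch_size, 128L)
  expect_equal(c(tc$lambda_spl, tc$lambda_ppl), c(1, 1))
})

test_that("the learning rate halves every halving period", {
  tc <- lfc_training_config()
  expect_equal(learning_rate(tc, 1), 1e-3)
  expect_equal(learning_rate(tc, 500), 1e-3)
  expect_equal(learning_rate(tc, 501), 5e-4)   # first halving
  expect_equal(learning_rate(tc, 1001), 2.5e-4)
  expect_equal(learning_rate(tc, 2000), 1.25e-4)
})

test_that("YAML configs mirror the training configuration", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("batch_size: 4", "epochs: 10", "lr_initial: 0.01",
               "patch_size: 16", "seed: 9"), f)
  tc <- read_training_config(f)
  expect_identical(tc$batch_size, 4L)
  expect_identical(tc$epochs, 10L)
  expect_equal(tc$lr_initial, 0.01)
  expect_identical(tc$lr_halving_period, 500L)  # unspecified fields keep defaults
  unlink(f)
})

test_that("patch sampling is reproducible, correctly shaped, and decomposed", {
  imgs <- lapply(1:3, function(i) generate_image("ct-phantom", 40, 40, seed = i))
  tc <- lfc_training_config(patch_size = 16L)
  p1 <- make_patches(imgs, tc, n_patches = 5, seed = 99)
  p2 <- make_patches(imgs, tc, n_patches = 5, seed = 99)
  expect_identical(p1, p2)
  p3 <- make_patches(imgs, tc, n_patches = 5, seed = 100)
  expect_false(identical(p1, p3))
  for (s in p1) {
    expect_s3_class(s, "subimage_set")
    expect_identical(dim(s$a), c(8L, 8L))
    expect_identical(c(s$orig_width, s$orig_height), c(16L, 16L))
  }
  expect_error(make_patches(imgs, lfc_training_config(patch_size = 64L)), "at least")
  expect_error(make_patches(tempfile(), tc), "directory|list")
})

test_that("training is deterministic under a fixed seed", {
  imgs <- lapply(1:2, function(i) generate_image("gradient", 24, 24, seed = i))
  cfg <- tiny_config(base_channels = 2L, n_scales = 1L)
  tc <- lfc_training_config(batch_size = 2L, epochs = 3L, lr_initial = 1e-2,
                            patch_size = 8L, seed = 5L)
  b1 <- lfc_train(imgs, cfg, tc)
  b2 <- lfc_train(imgs, cfg, tc)
  expect_identical(b1$version_hash, b2$version_hash)
  expect_identical(attr(b1, "history"), attr(b2, "history"))
  b3 <- lfc_train(imgs, cfg, lfc_training_config(batch_size = 2L, epochs = 3L,
                                                 lr_initial = 1e-2,
                                                 patch_size = 8L, seed = 6L))
  expect_false(identical(b3$version_hash, b1$version_hash))
})

test_that("training updates all three networks and logs per-epoch losses", {
  imgs <- lapply(1:2, function(i) generate_image("gradient", 24, 24, seed = i))
  cfg <- tiny_config(base_channels = 2L, n_scales = 1L)
  tc <- lfc_training_config(batch_size = 2L, epochs = 2L, lr_initial = 1e-2,
                            patch_size = 8L, seed = 5L)
  b <- lfc_train(imgs, cfg, tc)
  h <- attr(b, "history")
  expect_identical(nrow(h), 2L)
  expect_true(all(is.finite(h$loss)))
  expect_identical(h$lr, c(1e-2, 1e-2))
  u <- lfc_bundle(cfg, seed = 5L)
  for (k in 1:3)
    expect_false(identical(b$nets[[k]]$pre$cin$w, u$nets[[k]]$pre$cin$w))
})
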
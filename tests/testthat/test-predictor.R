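test_that("feature extraction obeys the shape contract and is bit-deterministic", {
  b <- test_bundle()
  sub <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
  mm1 <- extract_features(sub, b$nets[[1]])
  mm2 <- extract_features(sub, b$nets[[1]])
  expect_identical(dim(mm1), c(16L, 16L, b$config$base_channels))
  expect_identical(mm1, mm2)
  pred1 <- predict_subimage(mm1, b$nets[[1]])
  expect_identical(dim(pred1), c(16L, 16L))
  expect_identical(pred1, predict_subimage(mm2, b$nets[[1]]))
})

test_that("input-count and shape mismatches are rejected", {
  b <- test_bundle()
  sub <- matrix(0L, 8, 8)
  expect_error(extract_features(list(sub, sub), b$nets[[1]]), "expects 1")
  expect_error(extract_features(list(sub, matrix(0L, 8, 9)), b$nets[[2]]), "share one shape")
})

test_that("a zero image through zero parameters yields zero features", {
  ns <- asNamespace("lfc")
  net <- ns$with_seed(1, ns$init_net(1, tiny_config()))
  net <- ns$tree_map(function(x) x * 0, net[c("pre", "head", "unet")])
  net$n_inputs <- 1L
  mm <- extract_features(matrix(0L, 12, 12), net)
  expect_true(all(mm == 0))
})

test_that("the probability head emits a 511-channel simplex at every pixel", {
  b <- test_bundle()
  sub <- matrix(sample(0:255, 12 * 12, replace = TRUE), 12, 12)
  mm <- extract_features(sub, b$nets[[1]])
  pmf <- predict_residual_pmf(mm, b$nets[[1]], b$config)
  expect_identical(dim(pmf), c(12L, 12L, 511L))
  sums <- apply(pmf, c(1, 2), sum)
  expect_true(all(abs(sums - 1) <= 1e-5))
  expect_true(all(pmf >= 0))
})

test_that("softmax normalization holds for arbitrary random parameters", {
  set.seed(21)
  for (trial in 1:12) {
    b <- lfc_bundle(tiny_config(base_channels = sample(2:5, 1)),
                    seed = 500L + trial)
    # perturb all parameters so output layers are no longer zero
    b$nets[[1]][c("pre", "head", "unet")] <-
      rapply(b$nets[[1]][c("pre", "head", "unet")],
             function(x) x + rnorm(length(x), sd = 0.3),
             classes = "ANY", how = "replace")
    h <- sample(3:17, 1); w <- sample(3:17, 1)
    sub <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    mm <- extract_features(sub, b$nets[[1]])
    pmf <- predict_residual_pmf(mm, b$nets[[1]], b$config)
    expect_identical(dim(pmf), c(h, w, 511L))
    expect_true(all(abs(apply(pmf, c(1, 2), sum) - 1) <= 1e-5))
  }
})

test_that("dimensions not divisible by 2^n_scales go through pad-and-crop (4-scale net)", {
  cfg <- lfc_config(base_channels = 2L, n_scales = 4L)   # pad to multiples of 16
  b <- lfc_bundle(cfg, seed = 31)
  sub <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  mm <- extract_features(sub, b$nets[[1]])
  pmf <- predict_residual_pmf(mm, b$nets[[1]], cfg)
  expect_identical(dim(pmf), c(10L, 10L, 511L))
  expect_true(all(abs(apply(pmf, c(1, 2), sum) - 1) <= 1e-5))
})

test_that("infer() equals the composed pipeline, runs one evaluation, and is reproducible", {
  b <- test_bundle()
  sub <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  reset_inference_count()
  r1 <- infer(sub, b)
  expect_identical(inference_count(), 1L)
  mm <- extract_features(sub, b$nets[[1]])
  expect_identical(r1$prediction, predict_subimage(mm, b$nets[[1]]))
  expect_identical(r1$pmf, predict_residual_pmf(mm, b$nets[[1]], b$config))
  r2 <- infer(sub, b)
  expect_identical(r1, r2)
})

test_that("bundles refuse unsupported input counts and hash their parameters", {
  b <- test_bundle()
  expect_error(infer(list(matrix(0L, 4, 4), matrix(0L, 4, 4),
                          matrix(0L, 4, 4), matrix(0L, 4, 4)), b), "1-3")
  b2 <- lfc_bundle(tiny_config(), seed = 42L)
  expect_identical(b2$version_hash, b$version_hash)   # same seed, same params
  b3 <- lfc_bundle(tiny_config(), seed = 43L)
  expect_false(identical(b3$version_hash, b$version_hash))
  # any parameter change must change the hash
  b2$nets[[1]]$pre$cin$w[1] <- b2$nets[[1]]$pre$cin$w[1] + 1e-9
  expect_false(identical(bundle_hash(b2), b$version_hash))
})

test_that("checkpoints round-trip through save/load with integrity checking", {
  b <- test_bundle()
  f <- tempfile(fileext = ".ckpt")
  save_bundle(b, f)
  b2 <- load_bundle(f)
  expect_identical(b2$version_hash, b$version_hash)
  expect_identical(b2$nets, b$nets)
  unlink(f)
})
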
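# Shared fixtures.  Networks are desk-scale (4 channels, 2 scales) so the
# whole suite runs in minutes on one CPU; the probability head keeps the
# full 511-class output everywhere.

tiny_config <- function(base_channels = 4L, n_scales = 2L) {
  lfc_config(base_channels = base_channels, n_scales = n_scales)
}

.fixture_cache <- new.env(parent = emptyenv())

# untrained bundle shared across tests
test_bundle <- function() {
  if (is.null(.fixture_cache$untrained))
    .fixture_cache$untrained <- lfc_bundle(tiny_config(), seed = 42L)
  .fixture_cache$untrained
}

# smoke-trained bundle: short Adam run on synthetic linear ramps, trained
# once per test session
smoke_recipe <- function() {
  list(images = lapply(1:6, function(i) generate_image("gradient", 128, 128, seed = i)),
       config = tiny_config(),
       train = lfc_training_config(batch_size = 4L, epochs = 120L,
                                   lr_initial = 1e-2, lr_halving_period = 500L,
                                   patch_size = 32L, seed = 7L))
}

smoke_bundle <- function() {
  if (is.null(.fixture_cache$smoke)) {
    r <- smoke_recipe()
    .fixture_cache$smoke <- lfc_train(r$images, r$config, r$train)
  }
  .fixture_cache$smoke
}

# deterministic image battery mixing kinds, sizes and parities
random_test_image <- function(i, min_side = 8L, max_side = 128L) {
  kinds <- c("constant", "gradient", "gaussian-blobs", "uniform-noise", "ct-phantom")
  set.seed(10000L + i)
  w <- sample(min_side:max_side, 1L)
  h <- sample(min_side:max_side, 1L)
  generate_image(kinds[(i %% length(kinds)) + 1L], w, h, seed = 20000L + i)
}

expect_identical_image <- function(a, b) {
  expect_identical(unclass(a)[, , drop = FALSE], unclass(b)[, , drop = FALSE])
}

# random quantized CDFs for coder tests
random_cdf <- function(n_classes = 511L, precision = 16L, concentration = 1) {
  p <- rgamma(n_classes, shape = concentration)
  quantize_pmf(p / sum(p), precision)
}
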
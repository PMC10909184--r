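test_that("the prediction loss is the mean absolute pixel error", {
  y <- matrix(c(0, 10), 1, 2)
  expect_identical(spl_loss(y, y), 0)
  expect_equal(spl_loss(y, matrix(c(1, 8), 1, 2)), 1.5)
  # scalar loop oracle on random pairs
  set.seed(31)
  for (trial in 1:20) {
    h <- sample(1:12, 1); w <- sample(1:12, 1)
    a <- matrix(runif(h * w, 0, 255), h, w)
    p <- matrix(runif(h * w, -5, 260), h, w)
    acc <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) acc <- acc + abs(a[i, j] - p[i, j])
    expect_equal(spl_loss(a, p), acc / (h * w))
  }
  expect_error(spl_loss(y, matrix(0, 2, 2)), "mismatch")
})

test_that("the probability loss matches its closed forms", {
  onehot_pmf <- function(cls, h = 1, w = 1) {
    p <- array(0, c(h, w, 511)); p[, , cls + 1] <- 1; p
  }
  q <- matrix(100L, 1, 1)
  expect_equal(ppl_loss(q, onehot_pmf(100L)), 0)
  unif <- array(1 / 511, c(1, 1, 511))
  expect_equal(ppl_loss(matrix(255L, 1, 1), unif, uniform_weight_schedule()), log(511))
  # a weight-8 class observed with probability 1/2 costs 8 log 2
  p <- array(0, c(1, 1, 511)); p[1, 1, 51] <- 0.5; p[1, 1, 256] <- 0.5
  expect_equal(ppl_loss(matrix(50L, 1, 1), p), 8 * log(2))
  expect_error(ppl_loss(matrix(511L, 1, 1), unif), "\\[0, 510\\]")
})

test_that("unit weights reduce the weighted cross-entropy to plain cross-entropy", {
  set.seed(32)
  for (trial in 1:20) {
    h <- sample(1:9, 1); w <- sample(1:9, 1)
    z <- array(rnorm(h * w * 511), c(h, w, 511))
    pmf <- lfc:::softmax_ch(z)
    q <- matrix(sample(0:510, h * w, replace = TRUE), h, w)
    # independent plain cross-entropy
    ce <- 0
    for (i in seq_len(h)) for (j in seq_len(w)) ce <- ce - log(pmf[i, j, q[i, j] + 1])
    expect_equal(ppl_loss(q, pmf, uniform_weight_schedule()), ce / (h * w),
                 tolerance = 1e-9)
  }
})

test_that("both losses are nonnegative and vanish only at exactness", {
  set.seed(33)
  y <- matrix(runif(16, 0, 255), 4, 4)
  expect_gt(spl_loss(y, y + 0.01), 0)
  z <- array(rnorm(4 * 4 * 511), c(4, 4, 511))
  pmf <- lfc:::softmax_ch(z)
  q <- matrix(sample(0:510, 16, replace = TRUE), 4, 4)
  expect_gt(ppl_loss(q, pmf), 0)
})

test_that("the default weight schedule has the documented endpoints and symmetry", {
  ws <- default_weight_schedule()
  expect_true(all(schedule_weight(ws, 0:99) == 8))     # rare large residuals
  expect_true(all(schedule_weight(ws, 200:300) == 1))  # common near-zero residuals
  expect_identical(schedule_weight(ws, 50L), 8)
  expect_identical(schedule_weight(ws, 255L), 1)
  all_c <- 0:510
  expect_identical(schedule_weight(ws, all_c), schedule_weight(ws, 510L - all_c))
  # non-decreasing in residual magnitude
  mags <- schedule_weight(ws, 255:510)
  expect_true(all(diff(mags) >= 0))
  # invalid schedules are refused
  expect_error(weight_schedule(c(0, 200), c(199, 510), c(1, 2)), "symmetric")
  expect_error(weight_schedule(c(0, 300), c(299, 510), c(-1, -1)), "positive")
  expect_error(weight_schedule(0, 509, 1), "partition")
})

test_that("the total loss combines the two terms linearly through the lambdas", {
  cfg <- lfc_training_config()
  expect_equal(total_loss(2.5, 3.5, cfg), 6)   # default lambdas are 1: plain sum
  cfg0 <- lfc_training_config(lambda_ppl = 0)
  expect_equal(total_loss(2.5, 99, cfg0), 2.5)
  cfg2 <- lfc_training_config(lambda_spl = 2, lambda_ppl = 3)
  expect_equal(total_loss(1, 1, cfg2), 5)
  expect_equal(total_loss(2, 1, cfg2) - total_loss(1, 1, cfg2), 2)
  expect_error(total_loss(Inf, 1, cfg), "finite")
})
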
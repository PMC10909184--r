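test_that("generation is deterministic under a fixed seed and respects bounds", {
  for (kind in c("constant", "gradient", "gaussian-blobs", "uniform-noise",
                 "ct-phantom")) {
    a <- generate_image(kind, 31, 17, seed = 3)
    bimg <- generate_image(kind, 31, 17, seed = 3)
    expect_identical(a, bimg)
    expect_true(all(a >= 0L & a <= 255L))
    expect_identical(dim(a), c(17L, 31L))
    expect_false(identical(a, generate_image(kind, 31, 17, seed = 4)))
  }
})

test_that("constant images are constant and gradients have strictly monotone row means", {
  img <- generate_image("constant", 12, 9, seed = 1, value = 77)
  expect_true(all(img == 77L))
  for (seed in 1:5) {
    g <- generate_image("gradient", 40, 40, seed = seed)
    expect_true(all(diff(rowMeans(g)) > 0))
  }
})

test_that("the phantom mixes flat regions with sharp edges", {
  img <- generate_image("ct-phantom", 64, 64, seed = 11)
  # flat interior: many repeated values; sharp edges: large neighbor jumps
  expect_gt(max(table(img)), 200)
  expect_gt(max(abs(diff(img[, 32]))), 50)
})

test_that("the residual histogram conserves pixels and the report accounts every bit", {
  b <- test_bundle()
  img <- generate_image("ct-phantom", 30, 26, seed = 12)
  rep <- residual_report(img, b)
  # one residual per pixel of each predicted subimage (3 of 4 phases)
  expect_identical(sum(rep$histogram), 3L * 15L * 13L)
  expect_equal(rep$total_bpp,
               sum(rep$subimage_bpp) + rep$base_bpp + rep$header_bpp,
               tolerance = 1e-12)
  expect_identical(names(rep$subimage_bpp), c("D", "B", "C"))
})

test_that("the ablation harness emits the comparison table and is seed-stable", {
  imgs <- lapply(1:2, function(i) generate_image("gradient", 24, 24, seed = i))
  eval_imgs <- list(generate_image("gradient", 16, 16, seed = 50))
  cfg <- tiny_config(base_channels = 2L, n_scales = 1L)
  tc <- lfc_training_config(batch_size = 2L, epochs = 2L, lr_initial = 1e-2,
                            patch_size = 8L, seed = 3L)
  tab <- ablation_run(imgs, eval_imgs, cfg, tc)
  expect_identical(tab$Subimage, c("B", "C", "D", "Total"))
  expect_identical(names(tab), c("Subimage", "Model1", "Model2"))
  expect_true(all(tab$Model1 >= 0) && all(tab$Model2 >= 0))
  expect_equal(tab$Model1[4], sum(tab$Model1[1:3]), tolerance = 1e-12)
  # identical schedules + shared seed => identical columns
  tab2 <- ablation_run(imgs, eval_imgs, cfg, tc,
                       schedules = list(M1 = default_weight_schedule(),
                                        M2 = default_weight_schedule()))
  expect_identical(tab2$M1, tab2$M2)
})
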
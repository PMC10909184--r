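test_that("compress/decompress is the exact inverse on assorted shapes and codecs", {
  b <- test_bundle()
  shapes <- list(c(1, 1), c(2, 3), c(5, 5), c(8, 8), c(13, 9))
  set.seed(51)
  for (sh in shapes) {
    img <- matrix(sample(0:255, sh[1] * sh[2], replace = TRUE), sh[1], sh[2])
    for (codec in c("png", "store")) {
      st <- compress_image(img, b, base_codec = codec)
      expect_identical_image(decompress_image(st, b), gray_image(img))
    }
  }
})

test_that("the container header parses and payload lengths reconcile", {
  b <- test_bundle()
  img <- generate_image("gaussian-blobs", 21, 14, seed = 4)
  core <- lfc:::compress_core(img, b)
  st <- core$stream
  expect_identical(st[1:4], charToRaw("LFC1"))
  expect_identical(length(st), core$header_bytes + sum(core$payload_bytes))
  # declared lengths match the actual payload sizes
  lens <- vapply(0:3, function(i)
    lfc:::raw_to_u32(st[(29 + 4 * i):(32 + 4 * i)]), numeric(1))
  expect_identical(as.integer(lens),
                   as.integer(core$payload_bytes[c("a", "d", "b", "c")]))
})

test_that("tampering with any payload byte is caught", {
  b <- test_bundle()
  img <- generate_image("ct-phantom", 20, 20, seed = 6)
  st <- compress_image(img, b)
  set.seed(52)
  for (trial in 1:5) {
    bad <- st
    i <- sample((45):length(st), 1)
    bad[i] <- xor(bad[i], as.raw(0x40))
    expect_error(decompress_image(bad, b), "corrupt|checksum|\\[0, 255\\]|\\[0, 510\\]")
  }
})

test_that("a mismatched model is refused before any pixel is produced", {
  b <- test_bundle()
  img <- generate_image("gradient", 16, 16, seed = 7)
  st <- compress_image(img, b)
  other <- lfc_bundle(tiny_config(), seed = 999L)
  expect_error(decompress_image(st, other), "model mismatch")
})

test_that("a lossy base codec is rejected by the self-check", {
  b <- test_bundle()
  lossy <- list(id = 0L, name = "lossy",
                encode = function(m) as.raw(as.integer(m) %/% 2L),
                decode = function(bytes, h, w) matrix(as.integer(bytes) * 2L, h, w))
  img <- generate_image("uniform-noise", 10, 10, seed = 8)
  expect_error(compress_image(img, b, base_codec = lossy), "not lossless")
})

test_that("bits per pixel follows the definition and the payload accounting adds up", {
  expect_equal(bpp(800L, 80, 80), 1.0)
  expect_equal(bpp(1600L, 80, 80), 2.0)          # linear in stream length
  b <- test_bundle()
  img <- generate_image("ct-phantom", 33, 27, seed = 9)
  rep <- residual_report(img, b)
  expect_equal(rep$total_bpp,
               sum(rep$subimage_bpp) + rep$base_bpp + rep$header_bpp,
               tolerance = 1e-12)
  expect_gte(rep$total_bpp, max(rep$subimage_bpp))
})

test_that("compressing one image costs exactly three network inferences", {
  b <- test_bundle()
  img <- generate_image("gaussian-blobs", 18, 22, seed = 10)
  reset_inference_count()
  st <- compress_image(img, b)
  expect_identical(inference_count(), 3L)
  reset_inference_count()
  out <- decompress_image(st, b)
  expect_identical(inference_count(), 3L)
  expect_identical_image(out, img)
})
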
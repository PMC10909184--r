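#' Residual and rate accounting for one image
#'
#' Runs an actual compression pass and reports the per-class histogram of
#' the quantized residuals (all three predicted subimages pooled), the
#' per-subimage payload rates, and the total rate.  A well-trained model
#' on smooth material concentrates the histogram at class 255 (zero
#' residual); the per-subimage rates typically improve in the coding
#' order D, B, C as each network sees more context.
#'
#' @param image a [gray_image] or integer matrix.
#' @param bundle an [lfc_bundle()].
#' @param base_codec,precision as in [compress_image()].
#' @return an object of class `lfc_residual_report`: list with
#'   `histogram` (counts for classes 0-510, summing to the number of
#'   predicted-subimage pixels), `subimage_bpp` (named D, B, C),
#'   `base_bpp`, `header_bpp`, `total_bpp`, and `mode_class`.
#' @export
residual_report <- function(image, bundle, base_codec = "png", precision = 16L) {
  core <- compress_core(image, bundle, base_codec, precision)
  npx <- core$width * core$height
  sub_bpp <- vapply(c("d", "b", "c"),
                    function(nm) 8 * core$detail[[nm]]$n_bytes / npx, numeric(1))
  names(sub_bpp) <- c("D", "B", "C")
  structure(list(
    histogram = stats::setNames(core$histogram, 0:510),
    subimage_bpp = sub_bpp,
    base_bpp = 8 * core$payload_bytes[["a"]] / npx,
    header_bpp = 8 * core$header_bytes / npx,
    total_bpp = bpp(core$stream, core$width, core$height),
    mode_class = which.max(core$histogram) - 1L,
    n_pixels = npx
  ), class = "lfc_residual_report")
}

#' @export
print.lfc_residual_report <- function(x, ...) {
  cat("Residual report\n")
  cat(sprintf("  histogram mode: class %d (%d of %d residuals)\n",
              x$mode_class, max(x$histogram), sum(x$histogram)))
  cat("  rate accounting (bits per pixel of the original image):\n")
  for (nm in c("D", "B", "C"))
    cat(sprintf("    subimage %s : %7.4f\n", nm, x$subimage_bpp[[nm]]))
  cat(sprintf("    base (A)   : %7.4f\n", x$base_bpp))
  cat(sprintf("    header     : %7.4f\n", x$header_bpp))
  cat(sprintf("    total      : %7.4f\n", x$total_bpp))
  invisible(x)
}

#' Weighted-vs-plain cross-entropy ablation harness
#'
#' Trains two models that differ only in the residual class-weight
#' schedule -- by default model 1 uses plain (uniform-weight)
#' cross-entropy and model 2 the magnitude-weighted schedule -- under
#' identical seeds and data, then compares per-subimage compression rates
#' on evaluation images.  At desk scale no direction of difference is
#' asserted; the harness exists to produce the comparison table.
#'
#' @param train_data training images (directory, matrix, or list).
#' @param eval_images list of evaluation images.
#' @param config an [lfc_config()].
#' @param train_config an [lfc_training_config()].
#' @param schedules named list of exactly two [weight_schedule()] objects.
#' @param base_codec,precision as in [compress_image()].
#' @return a data frame with rows `B`, `C`, `D`, `Total` and one BPP
#'   column per model (mean over `eval_images`).
#' @export
ablation_run <- function(train_data, eval_images,
                         config = lfc_config(),
                         train_config = lfc_training_config(),
                         schedules = list(
                           Model1 = uniform_weight_schedule(),
                           Model2 = default_weight_schedule()),
                         base_codec = "png", precision = 16L) {
  stopifnot(length(schedules) == 2L)
  if (is.matrix(eval_images)) eval_images <- list(eval_images)
  cols <- lapply(schedules, function(sch) {
    bundle <- lfc_train(train_data, config, train_config, schedule = sch)
    reps <- lapply(eval_images, residual_report, bundle = bundle,
                   base_codec = base_codec, precision = precision)
    b <- rowMeans(vapply(reps, function(r) r$subimage_bpp, numeric(3)))
    c(B = b[["B"]], C = b[["C"]], D = b[["D"]], Total = sum(b))
  })
  out <- data.frame(Subimage = c("B", "C", "D", "Total"))
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
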
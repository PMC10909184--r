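#' Integerize a pixel prediction
#'
#' Rounds a real-valued pixel prediction half away from zero and clips to
#' \[0, 255\].  The prediction is integerized before the residual is
#' formed, so the residual is an exact integer difference and
#' reconstruction is exact under any deterministic inference -- the
#' codec's losslessness does not depend on floating-point tie conventions.
#'
#' @param pred real-valued matrix of predicted pixel values.
#' @return integer matrix in \[0, 255\].
#' @export
quantize_prediction <- function(pred) {
  if (any(!is.finite(pred)))
    stop("prediction contains non-finite values", call. = FALSE)
  out <- pmin(pmax(round_half_away(pred), 0), 255)
  matrix(as.integer(out), nrow(pred), ncol(pred))
}

#' Offset-255 quantized residual classes
#'
#' The residual between a true subimage and its integerized prediction is
#' shifted by +255 so that every class is a nonnegative integer:
#' `Q = (real - pred) + 255`.  With both operands in \[0, 255\] the classes
#' provably lie in \[0, 510\] (511 classes), with class 255 meaning a
#' perfect prediction.  [reconstruct_subimage()] inverts the operation
#' exactly: `real = pred + Q - 255`.
#'
#' @param real integer matrix in \[0, 255\] (the true subimage).
#' @param pred_i integer matrix in \[0, 255\] from [quantize_prediction()].
#' @return integer matrix of residual classes in \[0, 510\].
#' @export
quantized_residual <- function(real, pred_i) {
  if (!identical(dim(real), dim(pred_i)))
    stop("shape mismatch between subimage and prediction", call. = FALSE)
  assert_gray(real, "real")
  assert_gray(pred_i, "pred_i")
  matrix(as.integer(real) - as.integer(pred_i) + 255L, nrow(real), ncol(real))
}

#' @rdname quantized_residual
#' @param q integer matrix of residual classes in \[0, 510\].
#' @export
reconstruct_subimage <- function(pred_i, q) {
  if (!identical(dim(pred_i), dim(q)))
    stop("shape mismatch between prediction and residual", call. = FALSE)
  if (any(q < 0L) || any(q > 510L))
    stop("residual class outside [0, 510]", call. = FALSE)
  out <- as.integer(pred_i) + as.integer(q) - 255L
  if (any(out < 0L) || any(out > 255L))
    stop("corrupt stream: reconstructed pixel outside [0, 255]", call. = FALSE)
  matrix(out, nrow(pred_i), ncol(pred_i))
}
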
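#' Class-weight schedule for the residual cross-entropy
#'
#' Offset-255 residuals of a well-trained predictor concentrate sharply
#' around class 255, so a plain cross-entropy barely sees the rare large
#' residuals.  The weighted cross-entropy counters this imbalance with a
#' per-class weight that grows with the residual magnitude `|class - 255|`.
#' The default schedule puts weight 8 on classes 0-99 and 411-510 (the
#' rare large residuals), weight 1 on the common central band 200-310
#' (the smallest symmetric band containing classes 200-300), and a
#' symmetric doubling staircase in between (weight 4 on 100-149 and
#' 361-410, weight 2 on 150-199 and 311-360).  Any partition of \[0, 510\]
#' that is symmetric about class 255 with weights non-decreasing in
#' `|class - 255|` is accepted.
#'
#' @param lower,upper integer vectors of interval bounds (inclusive) that
#'   partition 0..510.
#' @param weights positive weight per interval.
#' @return an object of class `weight_schedule` with the intervals and an
#'   expanded 511-long `per_class` lookup vector.
#' @examples
#' ws <- default_weight_schedule()
#' schedule_weight(ws, c(50, 255, 460))
#' @export
weight_schedule <- function(lower, upper, weights) {
  stopifnot(length(lower) == length(upper), length(lower) == length(weights))
  o <- order(lower)
  lower <- as.integer(lower[o]); upper <- as.integer(upper[o]); weights <- weights[o]
  if (lower[1] != 0L || upper[length(upper)] != 510L ||
      any(lower[-1] != upper[-length(upper)] + 1L))
    stop("intervals must partition [0, 510] exactly", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  per_class <- rep(weights, upper - lower + 1L)
  if (any(per_class != rev(per_class)))
    stop("schedule must be symmetric about class 255", call. = FALSE)
  upperhalf <- per_class[256:511]
  if (any(diff(upperhalf) < 0))
    stop("weights must be non-decreasing in |class - 255|", call. = FALSE)
  structure(list(lower = lower, upper = upper, weights = weights,
                 per_class = per_class),
            class = "weight_schedule")
}

#' @rdname weight_schedule
#' @export
default_weight_schedule <- function() {
  weight_schedule(
    lower   = c(0, 100, 150, 200, 311, 361, 411),
    upper   = c(99, 149, 199, 310, 360, 410, 510),
    weights = c(8, 4, 2, 1, 2, 4, 8))
}

#' @rdname weight_schedule
#' @param schedule a `weight_schedule`.
#' @param classes integer vector of residual classes in \[0, 510\].
#' @export
schedule_weight <- function(schedule, classes) {
  stopifnot(inherits(schedule, "weight_schedule"))
  if (any(classes < 0L) || any(classes > 510L))
    stop("class outside [0, 510]", call. = FALSE)
  schedule$per_class[classes + 1L]
}

#' @rdname weight_schedule
#' @export
uniform_weight_schedule <- function() {
  weight_schedule(lower = 0, upper = 510, weights = 1)
}

#' @export
print.weight_schedule <- function(x, ...) {
  cat("<weight_schedule>\n")
  for (i in seq_along(x$lower))
    cat(sprintf("  classes %3d-%3d : weight %g\n", x$lower[i], x$upper[i], x$weights[i]))
  invisible(x)
}

#' Training losses
#'
#' `spl_loss()` is the subimage-prediction loss: the mean absolute
#' difference between predicted and true pixel values.  `ppl_loss()` is
#' the probability-prediction loss: a weighted cross-entropy of the
#' predicted residual distribution against the realized residual class,
#' `-(1/N) * sum_i w(q_i) * log p_i(q_i)` (natural log; probabilities are
#' floored at 1e-12 inside the log).  `total_loss()` combines them with
#' the lambda weights of a [lfc_training_config()] (both 1 by default, so
#' the total is a plain sum).
#'
#' @param y true subimage (matrix in \[0, 255\]).
#' @param y_hat real-valued prediction of the same shape.
#' @return a nonnegative scalar.
#' @export
spl_loss <- function(y, y_hat) {
  if (!identical(dim(y), dim(y_hat)))
    stop("shape mismatch", call. = FALSE)
  mean(abs(y - y_hat))
}

#' @rdname spl_loss
#' @param q integer matrix of residual classes in \[0, 510\].
#' @param pmf an H x W x 511 array of per-pixel residual distributions.
#' @param schedule a [weight_schedule()]; defaults to
#'   [default_weight_schedule()].
#' @export
ppl_loss <- function(q, pmf, schedule = default_weight_schedule()) {
  d <- dim(pmf)
  if (length(d) != 3L || !identical(dim(q), d[1:2]))
    stop("shape mismatch between classes and pmf", call. = FALSE)
  if (any(q < 0L) || any(q > 510L))
    stop("class outside [0, 510]", call. = FALSE)
  n <- length(q)
  pm <- matrix(pmf, n, d[3])
  p_true <- pm[cbind(seq_len(n), as.integer(q) + 1L)]
  w <- schedule_weight(schedule, as.integer(q))
  -mean(w * log(pmax(p_true, 1e-12)))
}

#' @rdname spl_loss
#' @param l_spl,l_ppl precomputed loss values.
#' @param config a [lfc_training_config()] supplying `lambda_spl` and
#'   `lambda_ppl`.
#' @export
total_loss <- function(l_spl, l_ppl, config = lfc_training_config()) {
  if (!is.finite(l_spl) || !is.finite(l_ppl))
    stop("losses must be finite", call. = FALSE)
  config$lambda_spl * l_spl + config$lambda_ppl * l_ppl
}
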
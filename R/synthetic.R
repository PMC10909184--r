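#' Synthetic grayscale test images
#'
#' Deterministic, seedable generators spanning the regimes a codec for
#' medical CT/X-ray material must handle: flat regions, smooth ramps,
#' soft structures, pure noise, and piecewise-smooth anatomy-like
#' phantoms with sharp edges.  These stand in for clinical datasets in
#' all tests; they emulate value ranges and edge structure, not the
#' texture statistics of real scanners.
#'
#' Kinds:
#' \describe{
#'   \item{constant}{every pixel equal (value drawn from the seed unless
#'     `value` is given).}
#'   \item{gradient}{a linear ramp down the rows plus a gentle column
#'     ramp; row means are strictly increasing.}
#'   \item{gaussian-blobs}{a few soft Gaussian bumps on a dark background
#'     plus mild noise.}
#'   \item{uniform-noise}{i.i.d. uniform pixels over \[0, 255\] -- the
#'     incompressible worst case.}
#'   \item{ct-phantom}{a disk "body" with internal rings and lesions
#'     (sharp boundaries, flat interiors) plus acquisition-like noise.}
#' }
#'
#' @param kind one of `"constant"`, `"gradient"`, `"gaussian-blobs"`,
#'   `"uniform-noise"`, `"ct-phantom"`.
#' @param width,height image dimensions in pixels.
#' @param seed RNG seed; the same spec always generates the same image.
#' @param noise_sigma additive Gaussian noise level in intensity units
#'   (defaults: 0 for constant/gradient/uniform-noise, 2 for blobs and
#'   phantom).
#' @param value fixed intensity for `kind = "constant"`.
#' @return a [gray_image].
#' @examples
#' img <- generate_image("ct-phantom", 64, 64, seed = 7)
#' @export
generate_image <- function(kind = c("constant", "gradient", "gaussian-blobs",
                                    "uniform-noise", "ct-phantom"),
                           width = 64L, height = 64L, seed = 1L,
                           noise_sigma = NULL, value = NULL) {
  kind <- match.arg(kind)
  stopifnot(width >= 1, height >= 1)
  if (is.null(noise_sigma))
    noise_sigma <- if (kind %in% c("gaussian-blobs", "ct-phantom")) 2 else 0
  with_seed(seed, {
    g <- switch(kind,
      constant = {
        v <- if (is.null(value)) sample(0:255, 1L) else value
        matrix(v, height, width)
      },
      gradient = {
        v0 <- runif(1, 0, 40); v1 <- runif(1, 200, 255)
        rowramp <- if (height > 1) v0 + (v1 - v0) * (seq_len(height) - 1) / (height - 1)
                   else rep((v0 + v1) / 2, 1)
        colramp <- if (width > 1) runif(1, -10, 10) * (seq_len(width) - 1) / (width - 1)
                   else 0
        outer(rowramp, rep(1, width)) + outer(rep(1, height), colramp)
      },
      `gaussian-blobs` = {
        bg <- runif(1, 10, 40)
        g <- matrix(bg, height, width)
        rr <- row(g); cc <- col(g)
        for (i in seq_len(sample(2:5, 1L))) {
          cy <- runif(1, 1, height); cx <- runif(1, 1, width)
          s <- runif(1, max(2, min(height, width) / 12), max(3, min(height, width) / 4))
          amp <- runif(1, 60, 200)
          g <- g + amp * exp(-((rr - cy)^2 + (cc - cx)^2) / (2 * s^2))
        }
        g
      },
      `uniform-noise` = matrix(floor(runif(height * width, 0, 256)), height, width),
      `ct-phantom` = {
        g <- matrix(0, height, width)
        rr <- row(g); cc <- col(g)
        cy <- height / 2 + runif(1, -height / 16, height / 16)
        cx <- width / 2 + runif(1, -width / 16, width / 16)
        body_r <- 0.42 * min(height, width)
        d <- sqrt((rr - cy)^2 + (cc - cx)^2)
        g[d <= body_r] <- runif(1, 90, 130)                 # soft tissue
        ring <- d <= body_r & d > body_r * runif(1, 0.85, 0.92)
        g[ring] <- runif(1, 200, 250)                       # bone shell
        for (i in seq_len(sample(2:4, 1L))) {               # lesions/organs
          lr <- runif(1, 0.05, 0.18) * min(height, width)
          ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, body_r * 0.6)
          ly <- cy + rad * sin(ang); lx <- cx + rad * cos(ang)
          dl <- sqrt((rr - ly)^2 + (cc - lx)^2)
          g[dl <= lr] <- runif(1, 30, 220)
        }
        g
      })
    if (noise_sigma > 0)
      g <- g + rnorm(length(g), sd = noise_sigma)
    gray_image(matrix(pmin(pmax(round_half_away(g), 0), 255), height, width))
  })
}
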
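#' Polyphase decomposition into four subimages
#'
#' Splits an image on its 2x2 sampling lattice: with 1-based indexing,
#' subimage A collects the odd-row/odd-column pixels, B odd-row/even-column,
#' C even-row/odd-column and D even-row/even-column, so A is the top-left
#' pixel of every 2x2 block.  Odd dimensions are first edge-replicated to
#' even size; the padding is recorded so [recompose_image()] can crop it
#' away.  The pair of operations is an exact bijection:
#' `recompose_image(decompose_image(x))` equals `x` for every image.
#'
#' @param image a [gray_image] or integer matrix in \[0, 255\].
#' @return an object of class `subimage_set`: a list with integer matrices
#'   `a`, `b`, `c`, `d` (all of identical dimensions), the original
#'   `orig_width`/`orig_height`, and `pad_flags` (logical `row`, `col`).
#' @seealso [recompose_image()]
#' @examples
#' s <- decompose_image(matrix(c(1, 3, 2, 4), 2, 2))
#' s$a  # top-left phase
#' @export
decompose_image <- function(image) {
  assert_gray(image)
  h <- nrow(image); w <- ncol(image)
  pad_row <- (h %% 2L) == 1L
  pad_col <- (w %% 2L) == 1L
  x <- unclass(image)
  if (pad_row) x <- rbind(x, x[h, , drop = FALSE])
  if (pad_col) x <- cbind(x, x[, ncol(x), drop = FALSE])
  ro <- seq(1L, nrow(x), 2L); re <- seq(2L, nrow(x), 2L)
  co <- seq(1L, ncol(x), 2L); ce <- seq(2L, ncol(x), 2L)
  structure(list(
    a = x[ro, co, drop = FALSE],
    b = x[ro, ce, drop = FALSE],
    c = x[re, co, drop = FALSE],
    d = x[re, ce, drop = FALSE],
    orig_width = w, orig_height = h,
    pad_flags = c(row = pad_row, col = pad_col)
  ), class = "subimage_set")
}

#' Recompose subimages into the original image
#'
#' Interleaves the four phase grids of a `subimage_set` back into a single
#' image and crops any edge-replication padding recorded at decomposition.
#'
#' @param subs a `subimage_set` as returned by [decompose_image()].
#' @return a [gray_image] of the original dimensions.
#' @export
recompose_image <- function(subs) {
  if (!inherits(subs, "subimage_set")) stop("not a subimage_set", call. = FALSE)
  dims <- lapply(subs[c("a", "b", "c", "d")], dim)
  if (length(unique(lapply(dims, as.integer))) != 1L &&
      !all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("subimage grids have mismatched shapes", call. = FALSE)
  h2 <- nrow(subs$a); w2 <- ncol(subs$a)
  out <- matrix(0L, 2L * h2, 2L * w2)
  ro <- seq(1L, 2L * h2, 2L); re <- seq(2L, 2L * h2, 2L)
  co <- seq(1L, 2L * w2, 2L); ce <- seq(2L, 2L * w2, 2L)
  out[ro, co] <- subs$a
  out[ro, ce] <- subs$b
  out[re, co] <- subs$c
  out[re, ce] <- subs$d
  gray_image(out[seq_len(subs$orig_height), seq_len(subs$orig_width), drop = FALSE])
}

#' @export
print.subimage_set <- function(x, ...) {
  cat(sprintf(
    "<subimage_set: 4 grids %d x %d, original %d x %d%s>\n",
    ncol(x$a), nrow(x$a), x$orig_width, x$orig_height,
    if (any(x$pad_flags)) " (edge-padded)" else ""))
  invisible(x)
}
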
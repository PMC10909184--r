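#' Grayscale image objects
#'
#' The codec's unit of work is an 8-bit single-channel image: an integer
#' matrix with values in \[0, 255\], rows indexing image rows (height) and
#' columns indexing image columns (width).  `gray_image()` validates a
#' matrix and stamps the class; most package functions accept plain
#' matrices and validate internally.
#'
#' @param x numeric or integer matrix with values in \[0, 255\].
#' @return an integer matrix of class `gray_image`.
#' @examples
#' img <- gray_image(matrix(0:3, 2, 2))
#' dim(img)
#' @export
gray_image <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 2L)
    stop("a grayscale image must be a 2-D matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("empty image: width and height must be at least 1", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("image contains non-finite values", call. = FALSE)
  if (any(x < 0) || any(x > 255) || any(x != round(x)))
    stop("image values must be integers in [0, 255]", call. = FALSE)
  y <- matrix(as.integer(x), nrow(x), ncol(x))
  class(y) <- c("gray_image", class(y))
  y
}

assert_gray <- function(x, arg = "image") {
  if (is.null(dim(x)) || length(dim(x)) != 2L || nrow(x) < 1L || ncol(x) < 1L)
    stop(arg, " must be a non-empty 2-D matrix", call. = FALSE)
  if (any(x < 0L) || any(x > 255L))
    stop(arg, " values must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d (width x height), range [%d, %d]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

# round half away from zero -- the single rounding convention used
# throughout the codec (platform-independent, unlike round()'s half-even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# ITU-R BT.601 luma for RGB -> gray conversion
rgb_to_gray <- function(arr) {
  g <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  round_half_away(g)
}

#' Read and write grayscale images
#'
#' `read_image()` loads a PNG or PGM file as a [gray_image]; RGB inputs are
#' converted to grayscale with the ITU-R BT.601 luma weights (0.299, 0.587,
#' 0.114) and rounded half away from zero.  `write_image()` writes PNG or
#' binary PGM (P5) depending on the file extension.  Both directions are
#' exact for 8-bit data: `read_image(write_image(x, f))` reproduces `x`.
#'
#' @param path file path; format chosen by extension (`.png`, `.pgm`).
#' @param image a [gray_image] or integer matrix in \[0, 255\].
#' @return `read_image()` returns a [gray_image]; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3] >= 3L) {
        g <- rgb_to_gray(arr * 255)
      } else {
        g <- round_half_away(arr[, , 1] * 255)
      }
    } else {
      g <- round_half_away(arr * 255)
    }
    gray_image(pmin(pmax(g, 0), 255))
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  assert_gray(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(unclass(image) / 255, target = path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else {
    stop("unsupported image format: ", ext, call. = FALSE)
  }
  invisible(path)
}

# PGM (P2 ascii / P5 binary, maxval <= 255)
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  tokens <- character(0)
  # read header tokens, skipping comments
  while (length(tokens) < 3L) {
    ch <- readBin(con, "raw", 1L)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    c1 <- rawToChar(ch)
    if (c1 == "#") {
      repeat {
        ch <- readBin(con, "raw", 1L)
        if (length(ch) == 0L || rawToChar(ch) == "\n") break
      }
    } else if (grepl("[0-9]", c1)) {
      tok <- c1
      repeat {
        ch <- readBin(con, "raw", 1L)
        if (length(ch) == 0L) break
        c2 <- rawToChar(ch)
        if (!grepl("[0-9]", c2)) break
        tok <- paste0(tok, c2)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (maxval > 255L) stop("only 8-bit PGM supported", call. = FALSE)
  n <- w * h
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n))
  } else if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    stop("not a PGM file (magic ", magic, ")", call. = FALSE)
  }
  if (length(vals) < n) stop("truncated PGM pixel data", call. = FALSE)
  gray_image(matrix(vals, nrow = h, ncol = w, byrow = TRUE))
}

write_pgm <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P5\n%d %d\n255\n", ncol(image), nrow(image))), con)
  writeBin(as.raw(as.integer(t(unclass(image)))), con)
  invisible(path)
}
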
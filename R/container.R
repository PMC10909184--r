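# ---- byte helpers --------------------------------------------------------

u32_to_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(c(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, (v %/% 16777216) %% 256))
}

raw_to_u32 <- function(r) {
  sum(as.numeric(r) * c(1, 256, 65536, 16777216))
}

hex_to_raw <- function(h) {
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
}

raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

image_checksum <- function(image) .crc32_cpp(as.raw(as.integer(image)))

# ---- base codecs ---------------------------------------------------------

#' Base codecs for subimage A
#'
#' The first polyphase subimage is stored with a conventional lossless
#' codec rather than predicted.  Available backends: `"png"` (default,
#' via the png package), `"store"` (uncompressed bytes), and `"jxl"`
#' (JPEG-XL, only when the external `cjxl`/`djxl` binaries are on the
#' PATH).  Every backend must be exactly lossless; the compressor
#' self-checks this on each run.
#'
#' @param name codec name or numeric id.
#' @return a list with `id`, `name`, `encode(matrix) -> raw` and
#'   `decode(raw, nrow, ncol) -> matrix`.
#' @export
lfc_base_codec <- function(name = "png") {
  if (is.numeric(name)) name <- c("store", "png", "jxl")[name + 1L]
  switch(name,
    store = list(
      id = 0L, name = "store",
      encode = function(m) as.raw(as.integer(m)),
      decode = function(bytes, h, w) matrix(as.integer(bytes), h, w)),
    png = list(
      id = 1L, name = "png",
      encode = function(m) png::writePNG(unclass(m) / 255, target = raw()),
      decode = function(bytes, h, w) {
        arr <- png::readPNG(bytes)
        if (length(dim(arr)) == 3L) arr <- arr[, , 1]
        out <- matrix(as.integer(round_half_away(arr * 255)), nrow(arr), ncol(arr))
        if (nrow(out) != h || ncol(out) != w)
          stop("corrupt stream: base payload has wrong dimensions", call. = FALSE)
        out
      }),
    jxl = {
      if (!nzchar(Sys.which("cjxl")) || !nzchar(Sys.which("djxl")))
        stop("jxl base codec requires cjxl/djxl on the PATH", call. = FALSE)
      list(
        id = 2L, name = "jxl",
        encode = function(m) {
          fin <- tempfile(fileext = ".pgm"); fout <- tempfile(fileext = ".jxl")
          on.exit(unlink(c(fin, fout)))
          write_pgm(m, fin)
          system2("cjxl", c("-d", "0", shQuote(fin), shQuote(fout)),
                  stdout = FALSE, stderr = FALSE)
          readBin(fout, "raw", file.info(fout)$size)
        },
        decode = function(bytes, h, w) {
          fin <- tempfile(fileext = ".jxl"); fout <- tempfile(fileext = ".pgm")
          on.exit(unlink(c(fin, fout)))
          writeBin(bytes, fin)
          system2("djxl", c(shQuote(fin), shQuote(fout)),
                  stdout = FALSE, stderr = FALSE)
          unclass(read_pgm(fout))
        })
    },
    stop("unknown base codec: ", name, call. = FALSE))
}

# ---- container -----------------------------------------------------------

LFC_MAGIC <- charToRaw("LFC1")
LFC_VERSION <- 1L
LFC_HEADER_LEN <- 44L

# core compression pass; also returns the per-subimage accounting used by
# residual_report()
compress_core <- function(image, bundle, base_codec = "png", precision = 16L) {
  assert_gray(image)
  stopifnot(inherits(bundle, "lfc_bundle"))
  if (precision < 10L || precision > 16L)
    stop("CDF precision must be in [10, 16] bits", call. = FALSE)
  codec <- if (is.list(base_codec)) base_codec else lfc_base_codec(base_codec)
  subs <- decompose_image(image)
  a_bytes <- codec$encode(subs$a)
  chk <- codec$decode(a_bytes, nrow(subs$a), ncol(subs$a))
  if (!identical(as.integer(chk), as.integer(subs$a)))
    stop("config error: base codec '", codec$name, "' is not lossless", call. = FALSE)
  payloads <- list(a = a_bytes)
  hist <- integer(511)
  detail <- list()
  for (stage in coding_order()) {
    inputs <- lapply(stage$inputs, function(nm) subs[[nm]])
    y <- subs[[stage$target]]
    r <- infer(inputs, bundle)
    pred_i <- quantize_prediction(r$prediction)
    q <- quantized_residual(y, pred_i)
    d <- dim(r$pmf)
    pm <- matrix(r$pmf, d[1] * d[2], d[3])
    bytes <- .rc_encode_pmf_cpp(pm, as.integer(q), as.integer(precision))
    payloads[[stage$target]] <- bytes
    hist <- hist + tabulate(as.integer(q) + 1L, nbins = 511L)
    detail[[stage$target]] <- list(n_bytes = length(bytes),
                                   classes = as.integer(q))
  }
  header <- c(
    LFC_MAGIC,
    as.raw(LFC_VERSION),
    as.raw(codec$id),
    as.raw(sum(c(1L, 2L)[subs$pad_flags])),
    as.raw(precision),
    u32_to_raw(subs$orig_width),
    u32_to_raw(subs$orig_height),
    hex_to_raw(bundle$version_hash),
    u32_to_raw(image_checksum(image)),
    u32_to_raw(length(payloads$a)),
    u32_to_raw(length(payloads$d)),
    u32_to_raw(length(payloads$b)),
    u32_to_raw(length(payloads$c))
  )
  stream <- c(header, payloads$a, payloads$d, payloads$b, payloads$c)
  list(stream = stream, header_bytes = length(header),
       payload_bytes = vapply(payloads, length, integer(1)),
       histogram = hist, detail = detail,
       width = subs$orig_width, height = subs$orig_height)
}

#' Compress and decompress grayscale images
#'
#' `compress_image()` runs the full pipeline: polyphase decomposition,
#' base-coding of subimage A, then -- for D, B and C in turn -- a single
#' network inference giving the pixel prediction and the 511-class
#' residual distributions, offset-255 residual quantization, and range
#' coding of the residual classes under the model's distributions.  The
#' result is a self-contained container (documented in FORMAT.md) whose
#' header records the original dimensions, padding, base codec, the model
#' version hash and a checksum of the original pixels.
#'
#' `decompress_image()` mirrors the pipeline: it decodes A, then
#' sequentially re-runs inference on already-decoded subimages to decode
#' and reconstruct D, B and C, recomposes the image, and verifies the
#' checksum.  Compression is exactly lossless:
#' `decompress_image(compress_image(x, b), b)` equals `x` bit for bit.
#'
#' @param image a [gray_image] or integer matrix in \[0, 255\].
#' @param bundle an [lfc_bundle()]; the decoder must be given a bundle
#'   with the same version hash that encoded the stream.
#' @param base_codec base codec name for subimage A (see
#'   [lfc_base_codec()]).
#' @param precision CDF quantization precision in bits.
#' @return `compress_image()` returns a raw vector; `decompress_image()`
#'   a [gray_image].
#' @export
compress_image <- function(image, bundle, base_codec = "png", precision = 16L) {
  compress_core(image, bundle, base_codec, precision)$stream
}

#' @rdname compress_image
#' @param stream a raw vector produced by `compress_image()`.
#' @export
decompress_image <- function(stream, bundle) {
  stopifnot(inherits(bundle, "lfc_bundle"))
  if (length(stream) < LFC_HEADER_LEN ||
      !identical(stream[1:4], LFC_MAGIC))
    stop("corrupt stream: bad magic", call. = FALSE)
  if (as.integer(stream[5]) != LFC_VERSION)
    stop("unsupported container version", call. = FALSE)
  codec <- lfc_base_codec(as.integer(stream[6]))
  padf <- as.integer(stream[7])
  pad_flags <- c(row = bitwAnd(padf, 1L) > 0L, col = bitwAnd(padf, 2L) > 0L)
  precision <- as.integer(stream[8])
  w <- raw_to_u32(stream[9:12])
  h <- raw_to_u32(stream[13:16])
  hash <- raw_to_hex(stream[17:24])
  if (!identical(hash, bundle$version_hash))
    stop("model mismatch: stream was encoded with bundle ", hash,
         " but decoder has ", bundle$version_hash, call. = FALSE)
  crc <- raw_to_u32(stream[25:28])
  lens <- vapply(0:3, function(i)
    raw_to_u32(stream[(29 + 4 * i):(32 + 4 * i)]), numeric(1))
  if (length(stream) != LFC_HEADER_LEN + sum(lens))
    stop("corrupt stream: declared payload lengths do not match", call. = FALSE)
  ofs <- LFC_HEADER_LEN
  take <- function(n) {
    out <- if (n > 0) stream[(ofs + 1):(ofs + n)] else raw(0)
    ofs <<- ofs + n
    out
  }
  h2 <- (h + h %% 2) / 2
  w2 <- (w + w %% 2) / 2
  subs <- list(a = NULL, b = NULL, c = NULL, d = NULL)
  subs$a <- tryCatch(codec$decode(take(lens[1]), h2, w2),
                     error = function(e)
                       stop("corrupt stream: base payload failed to decode (",
                            conditionMessage(e), ")", call. = FALSE))
  for (i in seq_along(coding_order())) {
    stage <- coding_order()[[i]]
    inputs <- lapply(stage$inputs, function(nm) subs[[nm]])
    r <- infer(inputs, bundle)
    pred_i <- quantize_prediction(r$prediction)
    d <- dim(r$pmf)
    pm <- matrix(r$pmf, d[1] * d[2], d[3])
    q <- .rc_decode_pmf_cpp(pm, take(lens[i + 1]), as.integer(h2 * w2),
                            as.integer(precision))
    subs[[stage$target]] <- reconstruct_subimage(pred_i, matrix(q, h2, w2))
  }
  set <- structure(list(a = subs$a, b = subs$b, c = subs$c, d = subs$d,
                        orig_width = w, orig_height = h,
                        pad_flags = pad_flags),
                   class = "subimage_set")
  out <- recompose_image(set)
  if (image_checksum(out) != crc)
    stop("corrupt stream: checksum failure after reconstruction", call. = FALSE)
  out
}

#' Bits per pixel
#'
#' Compressed size in bits divided by the pixel count of the original
#' image: `8 * bytes / (width * height)`.  Lower is better; 8 is the
#' uncompressed rate for 8-bit grayscale.
#'
#' @param stream a raw vector or a byte count.
#' @param width,height original image dimensions in pixels.
#' @return bits per pixel (numeric scalar).
#' @export
bpp <- function(stream, width, height) {
  stopifnot(width >= 1, height >= 1)
  n <- if (is.raw(stream)) length(stream) else as.numeric(stream)
  8 * n / (width * height)
}
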
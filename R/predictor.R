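#' Network configuration
#'
#' Sizes of the learned compressor's networks.  Each model bundle holds
#' three independent networks, one per number of already-coded input
#' subimages (1, 2 or 3); all three share the same configuration.  Every
#' network consists of a preprocessing feature extractor producing a shared
#' latent grid (the "middle matrix"), a small convolutional pixel-prediction
#' head, and a U-Net probability head whose softmax output has one channel
#' per quantized residual class.
#'
#' @param base_channels feature channels at the finest scale (default 64;
#'   doubled at each downward scale, capped at 512).
#' @param n_scales number of downward (and upward) processes in the
#'   probability U-Net (default 4).
#' @param n_classes number of residual classes (default 511, the full range
#'   of offset-255 residuals of 8-bit pixels).
#' @param resblock_depth residual blocks per scale (default 1).
#' @return an object of class `lfc_config`.
#' @export
lfc_config <- function(base_channels = 64L, n_scales = 4L, n_classes = 511L,
                       resblock_depth = 1L) {
  stopifnot(base_channels >= 1, n_scales >= 1, n_classes >= 2, resblock_depth >= 1)
  structure(list(base_channels = as.integer(base_channels),
                 n_scales = as.integer(n_scales),
                 n_classes = as.integer(n_classes),
                 resblock_depth = as.integer(resblock_depth)),
            class = "lfc_config")
}

#' @export
print.lfc_config <- function(x, ...) {
  cat(sprintf("<lfc_config: base_channels=%d, n_scales=%d, n_classes=%d, resblock_depth=%d>\n",
              x$base_channels, x$n_scales, x$n_classes, x$resblock_depth))
  invisible(x)
}

ch_at_scale <- function(cfg, s) min(cfg$base_channels * 2L^s, 512L)

rb_stack_init <- function(c, depth) lapply(seq_len(depth), function(i) rb_init(c))

rb_stack_fw <- function(x, ps) {
  caches <- vector("list", length(ps))
  for (i in seq_along(ps)) {
    r <- rb_fw(x, ps[[i]])
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

rb_stack_bw <- function(caches, dy, ps) {
  grads <- vector("list", length(ps))
  for (i in rev(seq_along(ps))) {
    r <- rb_bw(caches[[i]], dy, ps[[i]])
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

# one network = preprocessing + prediction head + probability U-Net
init_net <- function(n_inputs, cfg) {
  C <- cfg$base_channels
  S <- cfg$n_scales
  down <- lapply(seq_len(S), function(s) list(
    conv = conv_init(3, ch_at_scale(cfg, s - 1L), ch_at_scale(cfg, s)),
    rb = rb_stack_init(ch_at_scale(cfg, s), cfg$resblock_depth)))
  up <- lapply(seq_len(S), function(s) list(
    upc = conv_init(3, ch_at_scale(cfg, s), ch_at_scale(cfg, s - 1L)),
    fuse = conv_init(3, 2L * ch_at_scale(cfg, s - 1L), ch_at_scale(cfg, s - 1L)),
    rb = rb_stack_init(ch_at_scale(cfg, s - 1L), cfg$resblock_depth)))
  list(
    n_inputs = n_inputs,
    pre = list(cin = conv_init(3, n_inputs, C), rb = rb_stack_init(C, cfg$resblock_depth)),
    head = list(c1 = conv_init(3, C, C), c2 = conv_init(3, C, 1, zero = TRUE)),
    unet = list(enc0 = rb_stack_init(C, cfg$resblock_depth), down = down, up = up,
                out = conv_init(3, C, cfg$n_classes, zero = TRUE))
  )
}

# ---- forward / backward passes ------------------------------------------

fe_fw <- function(x, p) {
  z <- conv_fw(x, p$pre$cin)
  zr <- relu(z)
  r <- rb_stack_fw(zr, p$pre$rb)
  list(mm = r$y, cache = list(x = x, z = z, zr = zr, rb = r$caches))
}

fe_bw <- function(cache, dmm, p) {
  r <- rb_stack_bw(cache$rb, dmm, p$pre$rb)
  dz <- r$dx * (cache$z > 0)
  d0 <- conv_bw(cache$x, p$pre$cin, dz)
  list(grads = list(cin = list(w = d0$dw, b = d0$db), rb = r$grads))
}

head_fw <- function(mm, p) {
  h <- conv_fw(mm, p$head$c1)
  hr <- relu(h)
  raw <- conv_fw(hr, p$head$c2)
  list(raw = raw, cache = list(mm = mm, h = h, hr = hr))
}

head_bw <- function(cache, draw, p) {
  d2 <- conv_bw(cache$hr, p$head$c2, draw)
  dh <- d2$dx * (cache$h > 0)
  d1 <- conv_bw(cache$mm, p$head$c1, dh)
  list(dmm = d1$dx,
       grads = list(c1 = list(w = d1$dw, b = d1$db),
                    c2 = list(w = d2$dw, b = d2$db)))
}

unet_fw <- function(mm, p, cfg) {
  S <- cfg$n_scales
  d <- dim(mm)
  m <- 2L^S
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  pad <- pad_br_fw(mm, ph, pw)
  enc_out <- vector("list", S + 1L)   # features entering each skip
  dcache <- vector("list", S)
  r0 <- rb_stack_fw(pad$y, p$unet$enc0)
  enc_out[[1]] <- r0$y
  cur <- r0$y
  for (s in seq_len(S)) {
    cs <- conv_fw(cur, p$unet$down[[s]]$conv, stride = 2L)
    csr <- relu(cs)
    rbs <- rb_stack_fw(csr, p$unet$down[[s]]$rb)
    dcache[[s]] <- list(x = cur, cs = cs, csr = csr, rb = rbs$caches)
    cur <- rbs$y
    enc_out[[s + 1L]] <- cur
  }
  ucache <- vector("list", S)
  u <- cur
  for (s in rev(seq_len(S))) {
    uu <- upsample2_fw(u)
    uc <- conv_fw(uu, p$unet$up[[s]]$upc)
    ucr <- relu(uc)
    cc <- concat_ch(ucr, enc_out[[s]])
    fc <- conv_fw(cc, p$unet$up[[s]]$fuse)
    fcr <- relu(fc)
    rbu <- rb_stack_fw(fcr, p$unet$up[[s]]$rb)
    ucache[[s]] <- list(uu = uu, uc = uc, ucr = ucr, cc = cc, fc = fc,
                        fcr = fcr, rb = rbu$caches)
    u <- rbu$y
  }
  logits_p <- conv_fw(u, p$unet$out)
  logits <- logits_p[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  list(logits = logits,
       cache = list(pad = pad, enc0 = r0$caches, dcache = dcache,
                    ucache = ucache, u = u, dims = d,
                    pdims = dim(pad$y)))
}

unet_bw <- function(cache, dlogits, p, cfg) {
  S <- cfg$n_scales
  pd <- cache$pdims
  dlp <- array(0, c(pd[1], pd[2], dim(dlogits)[3]))
  dlp[seq_len(cache$dims[1]), seq_len(cache$dims[2]), ] <- dlogits
  dout <- conv_bw(cache$u, p$unet$out, dlp)
  grads <- list(out = list(w = dout$dw, b = dout$db),
                up = vector("list", S), down = vector("list", S))
  # walk the up path from finest (applied last) to deepest; du chains the
  # gradient along the decoder, denc collects the skip-connection gradients
  du <- dout$dx
  denc <- vector("list", S)
  for (s in seq_len(S)) {
    uc <- cache$ucache[[s]]
    rbw <- rb_stack_bw(uc$rb, du, p$unet$up[[s]]$rb)
    dfc <- rbw$dx * (uc$fc > 0)
    dfuse <- conv_bw(uc$cc, p$unet$up[[s]]$fuse, dfc)
    nc1 <- dim(uc$ucr)[3]
    ducr <- dfuse$dx[, , seq_len(nc1), drop = FALSE]
    denc[[s]] <- dfuse$dx[, , -seq_len(nc1), drop = FALSE]
    duc <- ducr * (uc$uc > 0)
    dupc <- conv_bw(uc$uu, p$unet$up[[s]]$upc, duc)
    du <- upsample2_bw(dupc$dx)
    grads$up[[s]] <- list(upc = list(w = dupc$dw, b = dupc$db),
                          fuse = list(w = dfuse$dw, b = dfuse$db),
                          rb = rbw$grads)
  }
  # du is now the gradient at the bottleneck; walk the encoder backwards,
  # adding each scale's skip gradient where the encoder feature was reused
  dcur <- du
  for (s in rev(seq_len(S))) {
    dc <- cache$dcache[[s]]
    rbw <- rb_stack_bw(dc$rb, dcur, p$unet$down[[s]]$rb)
    dcs <- rbw$dx * (dc$cs > 0)
    dconv <- conv_bw(dc$x, p$unet$down[[s]]$conv, dcs, stride = 2L)
    grads$down[[s]] <- list(conv = list(w = dconv$dw, b = dconv$db), rb = rbw$grads)
    dcur <- dconv$dx + denc[[s]]
  }
  r0 <- rb_stack_bw(cache$enc0, dcur, p$unet$enc0)
  grads$enc0 <- r0$grads
  dmm <- pad_br_bw(cache$pad, r0$dx)
  grads <- grads[c("enc0", "down", "up", "out")]
  list(dmm = dmm, grads = grads)
}

# per-pixel mean over the input channels, kept as a matrix even for 1x1 grids
input_mean <- function(x) {
  d <- dim(x)
  base <- matrix(x[, , 1], d[1], d[2])
  if (d[3] > 1L) {
    for (k in 2:d[3]) base <- base + matrix(x[, , k], d[1], d[2])
    base <- base / d[3]
  }
  base
}

# stack a list of subimage matrices into a normalized H x W x N input array
stack_inputs <- function(subimages) {
  if (is.matrix(subimages)) subimages <- list(subimages)
  d <- dim(subimages[[1]])
  for (s in subimages) {
    if (!identical(dim(s), d)) stop("input subimages must share one shape", call. = FALSE)
  }
  array(unlist(subimages, use.names = FALSE), c(d[1], d[2], length(subimages))) / 255
}

#' Feature extraction into the shared latent grid
#'
#' Runs the preprocessing network of one of the bundle's three networks on
#' a stack of already-coded subimages, producing the latent feature grid
#' ("middle matrix") that both the pixel-prediction head and the
#' probability U-Net consume.  The number of subimages must match the
#' network's configured input count.
#'
#' @param subimages a matrix or list of 1-3 integer matrices in \[0, 255\],
#'   all of identical dimensions (inputs are normalized to \[0, 1\]).
#' @param net one element of a bundle's `nets` list.
#' @return a numeric H x W x base_channels array with attribute
#'   `input_mean` (the per-pixel mean of the normalized inputs, used by the
#'   prediction head as its anchor).
#' @export
extract_features <- function(subimages, net) {
  x <- stack_inputs(subimages)
  if (dim(x)[3] != net$n_inputs)
    stop(sprintf("network expects %d input subimage(s), got %d",
                 net$n_inputs, dim(x)[3]), call. = FALSE)
  mm <- fe_fw(x, net)$mm
  attr(mm, "input_mean") <- input_mean(x)
  mm
}

#' Pixel prediction from the latent grid
#'
#' The prediction head maps the middle matrix to one real value per target
#' pixel (on the 0-255 scale, unclipped).  The head predicts an offset from
#' the mean of the normalized input subimages, so an untrained network
#' (zero-initialized final layer) already reproduces the
#' mean-of-available-subimages predictor.
#'
#' @param mm middle matrix from [extract_features()].
#' @param net the same network the features came from.
#' @return a numeric matrix of predicted pixel values.
#' @export
predict_subimage <- function(mm, net) {
  base <- attr(mm, "input_mean")
  if (is.null(base)) stop("middle matrix lacks its input_mean attribute", call. = FALSE)
  raw <- head_fw(mm, net)$raw
  255 * (base + matrix(raw, dim(raw)[1], dim(raw)[2]))
}

#' Residual class probabilities from the latent grid
#'
#' The probability U-Net maps the middle matrix through `n_scales` downward
#' and upward processes with skip concatenations and emits, per pixel, a
#' softmax distribution over the residual classes.  Spatial dimensions not
#' divisible by `2^n_scales` are reflect-padded internally and cropped
#' back, so the output always matches the input grid.
#'
#' @inheritParams predict_subimage
#' @param config the bundle's [lfc_config()].
#' @return an H x W x n_classes array; each per-pixel vector is
#'   nonnegative and sums to 1.
#' @export
predict_residual_pmf <- function(mm, net, config) {
  logits <- unet_fw(mm, net, config)$logits
  softmax_ch(logits)
}

#' Model bundles
#'
#' A bundle holds three independent networks -- one for each possible
#' number of already-coded input subimages (1, 2, 3) -- plus the shared
#' [lfc_config()] and a version hash over all parameters.  The hash is
#' stored in every compressed container so a decoder can refuse a
#' mismatched model.  `lfc_bundle()` creates an untrained bundle with
#' random features and zero-initialized output layers (so its pixel
#' predictor is the mean of its inputs and its residual distribution is
#' uniform); [lfc_train()] returns a trained one.
#'
#' @param config an [lfc_config()].
#' @param seed integer seed for parameter initialization.
#' @return an object of class `lfc_bundle` with elements `nets` (list of
#'   3), `config`, and `version_hash`.
#' @export
lfc_bundle <- function(config = lfc_config(), seed = 1L) {
  stopifnot(inherits(config, "lfc_config"))
  nets <- with_seed(seed, lapply(1:3, function(n) init_net(n, config)))
  b <- structure(list(nets = nets, config = config, version_hash = NULL),
                 class = "lfc_bundle")
  b$version_hash <- bundle_hash(b)
  b
}

#' @rdname lfc_bundle
#' @param bundle an `lfc_bundle`.
#' @export
bundle_hash <- function(bundle) {
  .fnv64_cpp(serialize(list(bundle$nets, unclass(bundle$config)), NULL, version = 2))
}

count_params <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, count_params, numeric(1))) else length(tree)
}

#' @export
print.lfc_bundle <- function(x, ...) {
  np <- sum(vapply(x$nets, function(n) count_params(n[c("pre", "head", "unet")]), numeric(1)))
  cat(sprintf("<lfc_bundle: 3 networks, %s parameters, hash %s%s>\n",
              format(np, big.mark = ","), x$version_hash,
              if (!is.null(attr(x, "history"))) ", trained" else ""))
  invisible(x)
}

#' @export
summary.lfc_bundle <- function(object, ...) {
  print(object)
  print(object$config)
  h <- attr(object, "history")
  if (!is.null(h)) {
    cat(sprintf("training: %d epochs, final loss %.4f (prediction %.4f, probability %.4f)\n",
                nrow(h), h$loss[nrow(h)], h$spl[nrow(h)], h$ppl[nrow(h)]))
  }
  invisible(object)
}

#' Single-pass inference for one subimage
#'
#' Runs exactly one network evaluation: the feature extractor builds the
#' middle matrix once, and both the pixel prediction and the residual
#' probability distribution are read off it.  The global counter reported
#' by [inference_count()] increases by one per call.
#'
#' @param subimages already-coded subimages (matrix or list of matrices).
#' @param bundle an [lfc_bundle()].
#' @return a list with `prediction` (real-valued matrix) and `pmf`
#'   (H x W x n_classes array).
#' @export
infer <- function(subimages, bundle) {
  stopifnot(inherits(bundle, "lfc_bundle"))
  n <- if (is.matrix(subimages)) 1L else length(subimages)
  if (n < 1L || n > 3L)
    stop("a bundle provides networks for 1-3 input subimages", call. = FALSE)
  net <- bundle$nets[[n]]
  mm <- extract_features(subimages, net)
  .lfc_state$inference_count <- .lfc_state$inference_count + 1L
  list(prediction = predict_subimage(mm, net),
       pmf = predict_residual_pmf(mm, net, bundle$config))
}

#' Save and load model bundles
#'
#' Checkpoints are serialized R objects holding the three parameter sets,
#' the configuration, and the version hash.
#'
#' @param bundle an [lfc_bundle()].
#' @param path checkpoint file path.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "lfc_bundle"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "lfc_bundle")) stop("not a model checkpoint", call. = FALSE)
  if (!identical(bundle_hash(b), b$version_hash))
    stop("checkpoint hash mismatch: file corrupted", call. = FALSE)
  b
}
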
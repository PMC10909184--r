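#' Training configuration
#'
#' Hyperparameters of the training loop.  The defaults are the reference
#' recipe: Adam with batch size 24, 2000 epochs, initial learning rate
#' 1e-3 halved every 500 epochs, random 128x128 grayscale patches, and
#' both loss weights at 1.  Desk-scale smoke runs override these with far
#' smaller values (see the methods vignette).
#'
#' @param batch_size patches per optimizer step.
#' @param epochs training epochs.
#' @param lr_initial initial Adam learning rate.
#' @param lr_halving_period epochs between learning-rate halvings.
#' @param patch_size side length (pixels) of random training crops.
#' @param lambda_spl,lambda_ppl weights of the prediction and probability
#'   losses in the total loss.
#' @param batches_per_epoch optimizer steps per epoch.
#' @param seed RNG seed controlling initialization and patch sampling.
#' @return an object of class `lfc_training_config`.
#' @export
lfc_training_config <- function(batch_size = 24L, epochs = 2000L,
                                lr_initial = 1e-3, lr_halving_period = 500L,
                                patch_size = 128L, lambda_spl = 1,
                                lambda_ppl = 1, batches_per_epoch = 1L,
                                seed = 1L) {
  stopifnot(batch_size >= 1, epochs >= 1, lr_initial > 0,
            lr_halving_period >= 1, patch_size >= 2,
            lambda_spl >= 0, lambda_ppl >= 0, batches_per_epoch >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 lr_initial = lr_initial,
                 lr_halving_period = as.integer(lr_halving_period),
                 patch_size = as.integer(patch_size),
                 lambda_spl = lambda_spl, lambda_ppl = lambda_ppl,
                 batches_per_epoch = as.integer(batches_per_epoch),
                 seed = as.integer(seed)),
            class = "lfc_training_config")
}

#' @rdname lfc_training_config
#' @param path YAML file mirroring the configuration fields.
#' @export
read_training_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(lfc_training_config, vals)
}

#' @rdname lfc_training_config
#' @param config an `lfc_training_config`.
#' @param epoch 1-based epoch number.
#' @return `learning_rate()` returns the stepped-decay rate
#'   `lr_initial * 0.5^floor((epoch - 1) / lr_halving_period)`.
#' @export
learning_rate <- function(config, epoch) {
  config$lr_initial * 0.5^((epoch - 1L) %/% config$lr_halving_period)
}

# coding order: subimage A is base-coded; D, B, C are predicted in turn
# from everything already coded
coding_order <- function() {
  list(list(inputs = "a", target = "d"),
       list(inputs = c("a", "d"), target = "b"),
       list(inputs = c("a", "d", "b"), target = "c"))
}

load_training_images <- function(data) {
  if (is.character(data) && length(data) == 1L && dir.exists(data)) {
    files <- list.files(data, pattern = "\\.(png|pgm)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (length(files) == 0L)
      stop("no readable images in ", data, call. = FALSE)
    lapply(files, read_image)
  } else if (is.matrix(data)) {
    list(data)
  } else if (is.list(data) && length(data) > 0L) {
    lapply(data, function(x) { assert_gray(x); x })
  } else {
    stop("training data must be a directory or a list of images", call. = FALSE)
  }
}

#' Random training patches
#'
#' Samples random square crops from a set of grayscale images and
#' decomposes each into its four polyphase subimages, yielding the
#' supervision tuples for the three networks (inputs A; A,D; A,D,B with
#' targets D, B, C).  Sampling is reproducible under a fixed seed.
#'
#' @param data a directory of PNG/PGM images, a single matrix, or a list
#'   of matrices (RGB files are converted to grayscale on load).
#' @param config an [lfc_training_config()] supplying `patch_size`.
#' @param n_patches number of patches to draw.
#' @param seed RNG seed.
#' @return a list of `subimage_set` objects, one per patch.
#' @export
make_patches <- function(data, config = lfc_training_config(), n_patches = 1L,
                         seed = config$seed) {
  imgs <- load_training_images(data)
  ps <- config$patch_size
  usable <- Filter(function(x) nrow(x) >= ps && ncol(x) >= ps, imgs)
  if (length(usable) == 0L)
    stop("no image is at least ", ps, "x", ps, " pixels", call. = FALSE)
  with_seed(seed, lapply(seq_len(n_patches), function(i) {
    img <- usable[[sample.int(length(usable), 1L)]]
    r0 <- sample.int(nrow(img) - ps + 1L, 1L)
    c0 <- sample.int(ncol(img) - ps + 1L, 1L)
    decompose_image(img[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L), drop = FALSE])
  }))
}

# forward + backward for one (net, sample) pair; returns losses and grads
train_sample <- function(net, cfg, subs, inputs, target, tcfg, schedule) {
  x <- stack_inputs(lapply(inputs, function(nm) subs[[nm]]))
  y <- subs[[target]]
  fe <- fe_fw(x, net)
  base <- input_mean(x)
  hd <- head_fw(fe$mm, net)
  pred <- 255 * (base + matrix(hd$raw, nrow(y), ncol(y)))
  l_spl <- mean(abs(y - pred))
  pred_i <- quantize_prediction(pred)
  q <- quantized_residual(y, pred_i)
  un <- unet_fw(fe$mm, net, cfg)
  probs <- softmax_ch(un$logits)
  npix <- length(y)
  d <- dim(probs)
  pm <- matrix(probs, npix, d[3])
  idx <- cbind(seq_len(npix), as.integer(q) + 1L)
  w <- schedule_weight(schedule, as.integer(q))
  l_ppl <- -mean(w * log(pmax(pm[idx], 1e-12)))
  # gradients
  dlogits_m <- pm * (w / npix)
  dlogits_m[idx] <- dlogits_m[idx] - w / npix
  dlogits <- array(tcfg$lambda_ppl * dlogits_m, d)
  dpred <- tcfg$lambda_spl * sign(pred - y) / npix
  draw <- array(255 * dpred, c(nrow(y), ncol(y), 1L))
  hb <- head_bw(hd$cache, draw, net)
  ub <- unet_bw(un$cache, dlogits, net, cfg)
  feb <- fe_bw(fe$cache, hb$dmm + ub$dmm, net)
  list(spl = l_spl, ppl = l_ppl,
       grads = list(pre = feb$grads, head = hb$grads, unet = ub$grads))
}

#' Train a model bundle
#'
#' Trains the three networks jointly on the combined loss
#' `lambda_spl * L_pred + lambda_ppl * L_prob`, each network supervised on
#' its own target subimage with ground-truth subimages as teacher inputs
#' (equivalent to coded inputs, since coding is lossless).  Optimization
#' is Adam with the stepped learning-rate decay of [learning_rate()].
#' Training is deterministic under a fixed seed: two runs with the same
#' data and configuration produce bundles with identical version hashes.
#'
#' @param data training images: a directory path, a matrix, or a list of
#'   matrices.
#' @param config an [lfc_config()] describing the network sizes.
#' @param train_config an [lfc_training_config()].
#' @param schedule residual class-weight schedule for the cross-entropy
#'   (default [default_weight_schedule()]).
#' @param verbose print per-epoch losses.
#' @return a trained [lfc_bundle()] with a `history` attribute: a data
#'   frame of per-epoch learning rate and losses.
#' @export
lfc_train <- function(data, config = lfc_config(),
                      train_config = lfc_training_config(),
                      schedule = default_weight_schedule(),
                      verbose = FALSE) {
  stopifnot(inherits(config, "lfc_config"),
            inherits(train_config, "lfc_training_config"))
  imgs <- load_training_images(data)
  bundle <- lfc_bundle(config, seed = train_config$seed)
  opt <- lapply(bundle$nets, function(n) adam_init(n[c("pre", "head", "unet")]))
  ord <- coding_order()
  hist <- data.frame(epoch = integer(0), lr = numeric(0), loss = numeric(0),
                     spl = numeric(0), ppl = numeric(0))
  step_seed <- train_config$seed
  for (epoch in seq_len(train_config$epochs)) {
    lr <- learning_rate(train_config, epoch)
    ep_spl <- 0; ep_ppl <- 0; nb <- 0L
    for (b in seq_len(train_config$batches_per_epoch)) {
      step_seed <- (step_seed * 69069 + 1) %% 2147483647
      batch <- make_patches(imgs, train_config,
                            n_patches = train_config$batch_size,
                            seed = step_seed)
      for (k in 1:3) {
        net <- bundle$nets[[k]]
        gacc <- NULL
        spl_acc <- 0; ppl_acc <- 0
        for (subs in batch) {
          r <- train_sample(net, config, subs, ord[[k]]$inputs, ord[[k]]$target,
                            train_config, schedule)
          spl_acc <- spl_acc + r$spl
          ppl_acc <- ppl_acc + r$ppl
          gacc <- if (is.null(gacc)) r$grads else tree_add(gacc, r$grads)
        }
        m <- length(batch)
        gacc <- tree_map(function(g) g / m, gacc)
        st <- adam_step(net[c("pre", "head", "unet")], gacc, opt[[k]], lr)
        bundle$nets[[k]][c("pre", "head", "unet")] <- st$params
        opt[[k]] <- st$state
        ep_spl <- ep_spl + spl_acc / m
        ep_ppl <- ep_ppl + ppl_acc / m
      }
      nb <- nb + 1L
    }
    ep_spl <- ep_spl / (3 * nb)
    ep_ppl <- ep_ppl / (3 * nb)
    tot <- total_loss(ep_spl, ep_ppl, train_config)
    if (!is.finite(tot)) stop("training diverged: non-finite loss", call. = FALSE)
    hist <- rbind(hist, data.frame(epoch = epoch, lr = lr, loss = tot,
                                   spl = ep_spl, ppl = ep_ppl))
    if (verbose)
      message(sprintf("epoch %4d  lr %.2e  loss %.4f (pred %.4f, prob %.4f)",
                      epoch, lr, tot, ep_spl, ep_ppl))
  }
  bundle$version_hash <- bundle_hash(bundle)
  attr(bundle, "history") <- hist
  bundle
}
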
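# Minimal convolutional-network toolkit: forward/backward primitives over
# H x W x C arrays, parameter trees as nested lists of arrays, and Adam.
# All heavy kernels live in src/nn_ops.cpp; everything is deterministic
# double precision so encoder and decoder reproduce identical activations.

conv_init <- function(k, ci, co, zero = FALSE) {
  w <- if (zero) array(0, c(k, k, ci, co))
  else array(rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))), c(k, k, ci, co))
  list(w = w, b = numeric(co))
}

conv_fw <- function(x, p, stride = 1L) {
  .conv2d_fw_cpp(x, dim(x), p$w, dim(p$w), p$b, as.integer(stride))
}

conv_bw <- function(x, p, dy, stride = 1L) {
  .conv2d_bw_cpp(x, dim(x), p$w, dim(p$w), dy, as.integer(stride))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# residual block: x + conv(relu(conv(x))), channel-preserving
rb_init <- function(c) list(c1 = conv_init(3, c, c), c2 = conv_init(3, c, c))

rb_fw <- function(x, p) {
  h1 <- conv_fw(x, p$c1)
  h1r <- relu(h1)
  y <- x + conv_fw(h1r, p$c2)
  list(y = y, cache = list(x = x, h1 = h1, h1r = h1r))
}

rb_bw <- function(cache, dy, p) {
  d2 <- conv_bw(cache$h1r, p$c2, dy)
  dh1 <- d2$dx * (cache$h1 > 0)
  d1 <- conv_bw(cache$x, p$c1, dh1)
  list(dx = dy + d1$dx,
       grads = list(c1 = list(w = d1$dw, b = d1$db),
                    c2 = list(w = d2$dw, b = d2$db)))
}

# nearest-neighbour 2x upsampling
upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2_bw <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1L, d[1], 2L); e1 <- seq(2L, d[1], 2L)
  o2 <- seq(1L, d[2], 2L); e2 <- seq(2L, d[2], 2L)
  dy[o1, o2, , drop = FALSE] + dy[o1, e2, , drop = FALSE] +
    dy[e1, o2, , drop = FALSE] + dy[e1, e2, , drop = FALSE]
}

# bottom/right reflect padding indices (bounce pattern; degenerates to
# replication when the dimension is 1)
reflect_idx <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  pattern <- if (n > 2L) c(seq_len(n), seq(n - 1L, 2L)) else seq_len(n)
  rep_len(pattern, n + p)
}

pad_br_fw <- function(x, ph, pw) {
  d <- dim(x)
  ri <- reflect_idx(d[1], ph); ci <- reflect_idx(d[2], pw)
  list(y = x[ri, ci, , drop = FALSE], ridx = ri, cidx = ci, dim = d)
}

pad_br_bw <- function(cache, dy) {
  d <- cache$dim
  dp <- dim(dy)
  # collapse padded rows onto their source rows, then padded columns
  m <- rowsum(matrix(dy, dp[1], dp[2] * d[3]), group = cache$ridx)
  a <- array(m, c(d[1], dp[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  m <- rowsum(matrix(a, dp[2], d[1] * d[3]), group = cache$cidx)
  aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
}

concat_ch <- function(x1, x2) {
  d1 <- dim(x1); d2 <- dim(x2)
  array(c(x1, x2), c(d1[1], d1[2], d1[3] + d2[3]))
}

# channelwise softmax over an H x W x C array (C++ kernel)
softmax_ch <- function(z) .softmax_ch_cpp(z, dim(z))

# ---- parameter-tree utilities -------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(el) tree_map(f, el)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_add <- function(a, b) tree_map2(`+`, a, b)
tree_zero <- function(a) tree_map(function(x) x * 0, a)

# ---- Adam ---------------------------------------------------------------

adam_init <- function(params) list(m = tree_zero(params), v = tree_zero(params), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps), state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}
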
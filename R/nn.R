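# Minimal convolutional-network engine backing the multi-channel cycleGAN.
#
# Tensors are H x W x C arrays (single image per step; the model trains with
# batch size 1, the original cycleGAN convention). Convolutions are computed
# by gathering k x k x C patches into a column matrix (im2col) and
# multiplying by the weight matrix; transposed convolutions and input
# gradients reuse the same index structure through the scatter-add adjoint
# (col2im). Index structures are cached per (shape, kernel, stride, pad).

.conv_cache <- new.env(parent = emptyenv())

conv_struct <- function(h, w, c_in, k, stride, pad) {
  key <- paste(h, w, c_in, k, stride, pad, sep = "|")
  cached <- .conv_cache[[key]]
  if (!is.null(cached)) return(cached)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  ki <- rep(seq_len(k), times = k * c_in)
  kj <- rep(rep(seq_len(k), each = k), times = c_in)
  cc <- rep(seq_len(c_in), each = k * k)
  patch_off <- (ki - 1L) + (kj - 1L) * hp + (cc - 1L) * hp * wp
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  base <- (oi - 1L) * stride + (oj - 1L) * stride * hp
  idx <- outer(patch_off, base, "+") + 1L
  s <- list(h = h, w = w, c_in = c_in, k = k, stride = stride, pad = pad,
            hp = hp, wp = wp, ho = ho, wo = wo, idx = idx,
            targets = sort(unique(as.vector(idx))))
  .conv_cache[[key]] <- s
  s
}

pad_spatial <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

im2col <- function(x, s) {
  xp <- pad_spatial(x, s$pad)
  matrix(xp[s$idx], nrow(s$idx))
}

# adjoint of im2col: scatter-add columns back into a (padded, then cropped)
# image
col2im <- function(cols, s) {
  acc <- rowsum(as.vector(cols), group = as.vector(s$idx))
  flat <- numeric(s$hp * s$wp * s$c_in)
  flat[s$targets] <- acc
  xp <- array(flat, c(s$hp, s$wp, s$c_in))
  if (s$pad == 0L) return(xp)
  xp[s$pad + seq_len(s$h), s$pad + seq_len(s$w), , drop = FALSE]
}

# strided convolution; W is (k*k*c_in) x c_out, b length c_out
conv_fwd <- function(x, W, b, s) {
  cols <- im2col(x, s)
  out <- t(cols) %*% W
  out <- sweep(out, 2, b, "+")
  list(y = array(out, c(s$ho, s$wo, ncol(W))), cols = cols)
}

conv_bwd <- function(dy, W, s, cols) {
  dmat <- matrix(dy, s$ho * s$wo, ncol(W))
  list(dW = cols %*% dmat,
       db = colSums(dmat),
       dx = col2im(W %*% t(dmat), s))
}

# transposed convolution upsampling (hi, wi, c_in) -> (stride*hi, stride*wi,
# c_out) for k = 2*stride, pad = stride/2; W is (k*k*c_out) x c_in.
# `s` must be conv_struct(ho_out, wo_out, c_out, k, stride, pad) so that the
# conv's *output* grid equals this layer's input grid.
convT_fwd <- function(x, W, b, s) {
  xmat <- matrix(x, s$ho * s$wo, ncol(W))
  y <- col2im(W %*% t(xmat), s)
  for (c in seq_len(s$c_in)) y[, , c] <- y[, , c] + b[c]
  list(y = y, xmat = xmat)
}

convT_bwd <- function(dy, W, s, xmat) {
  cols_dy <- im2col(dy, s)
  list(dW = cols_dy %*% xmat,
       db = as.vector(apply(dy, 3, sum)),
       dx = array(t(cols_dy) %*% W, c(s$ho, s$wo, ncol(W))))
}

# instance normalization with affine parameters (per-channel over H, W)
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colSums(xc^2) / n
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

inorm_bwd <- function(dy, gamma, cache) {
  d <- cache$d; n <- d[1] * d[2]
  dym <- matrix(dy, n, d[3])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, "*")
  # dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$istd, "*")
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

lrelu_fwd <- function(x, slope = 0.2) list(y = pmax(x, 0) + slope * pmin(x, 0), x = x)
lrelu_bwd <- function(dy, x, slope = 0.2) dy * ifelse(x > 0, 1, slope)
relu_fwd <- function(x) list(y = pmax(x, 0), x = x)
relu_bwd <- function(dy, x) dy * (x > 0)
sigmoid_fwd <- function(x) { y <- 1 / (1 + exp(-x)); list(y = y) }
sigmoid_bwd <- function(dy, y) dy * y * (1 - y)

# parameter initialization: weights N(0, 0.02), biases 0, norm scale 1
init_param <- function(shape, kind) {
  n <- prod(shape)
  v <- switch(kind,
              weight = stats::rnorm(n, sd = 0.02),
              bias = rep(0, n),
              gamma = rep(1, n),
              beta = rep(0, n))
  if (length(shape) > 1L) matrix(v, shape[1], shape[2]) else v
}

zero_like <- function(p) lapply(p, function(x) x * 0)

grad_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t; b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}
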
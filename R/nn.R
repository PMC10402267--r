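# Internal neural-network primitives.
#
# 2D (encoder) convolutions are evaluated as GEMMs over C++ patch matrices:
#   Y = im2col(X) %*% matrix(W)      (forward)
#   dW = t(cols) %*% dY;  dX = col2im(dY %*% t(W))   (backward)
# 3D (decoder) convolutions use direct C++ kernels instead - their patch
# matrices would be too large to re-allocate every step. Transposed
# (up-)convolution is zero-insertion upsampling followed by a stride-1
# "same" convolution, a learnable linear map that exactly doubles each
# spatial axis. Gradient accumulation and Adam mutate in place to avoid
# churning the ~5M-double parameter set.

conv2d_f <- function(x, W, b, stride = 1L, pad = NULL) {
  k <- dim(W)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  d <- dim(x)
  cin <- dim(W)[3]; cout <- dim(W)[4]
  stopifnot(d[3] == cin)
  cols <- .im2col2d(as.numeric(x), d[1], d[2], d[3], k, stride, pad)
  y <- cols %*% matrix(W, k * k * cin, cout)
  y <- sweep(y, 2L, b, `+`)
  oh <- (d[1] + 2L * pad - k) %/% stride + 1L
  ow <- (d[2] + 2L * pad - k) %/% stride + 1L
  list(out = array(y, c(oh, ow, cout)), cols = cols, in_dim = d,
       stride = stride, pad = pad)
}

conv2d_b <- function(dout, W, cache) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  dY <- matrix(dout, ncol = cout)
  dW <- array(crossprod(cache$cols, dY), dim(W))
  db <- colSums(dY)
  dcols <- tcrossprod(dY, matrix(W, k * k * cin, cout))
  dx <- array(.col2im2d(dcols, cache$in_dim[1], cache$in_dim[2],
                        cache$in_dim[3], k, cache$stride, cache$pad),
              cache$in_dim)
  list(dx = dx, dW = dW, db = db)
}

# stride-1 3D convolution via direct C++ kernels (no patch matrices)
conv3d_f <- function(x, W, b, pad = NULL) {
  k <- dim(W)[1]
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  stopifnot(dim(x)[4] == dim(W)[4])
  y <- .conv3d_fwd(x, dim(x), W, b, k, pad)
  list(out = y, x = x, pad = pad)
}

conv3d_b <- function(dout, W, cache) {
  k <- dim(W)[1]; cout <- dim(W)[5]
  db <- colSums(matrix(dout, ncol = cout))
  dW <- .conv3d_bwd_w(cache$x, dim(cache$x), dout, dim(dout), k, cache$pad)
  dx <- array(.conv3d_bwd_x(dout, dim(dout), W, dim(cache$x), k, cache$pad),
              dim(cache$x))
  list(dx = dx, dW = dW, db = db)
}

# leaky rectifier: avoids dead-unit collapse in narrow layers
LRELU_SLOPE <- 0.1

relu_f <- function(x) {
  list(out = pmax(x, 0) + LRELU_SLOPE * pmin(x, 0), mask = x > 0)
}

relu_b <- function(dout, mask)
  dout * (LRELU_SLOPE + (1 - LRELU_SLOPE) * mask)

dense_f <- function(x, W, b) {
  x <- as.numeric(x)
  list(out = as.numeric(x %*% W) + b, x = x)
}

dense_b <- function(dout, W, cache) {
  list(dx = as.numeric(W %*% dout),
       dW = tcrossprod(cache$x, dout), db = dout)
}

# zero-insertion x2 upsampling of a (h, w, d, C) feature map
zstuff3_f <- function(x) {
  d <- dim(x)
  y <- array(0, c(2L * d[1:3], d[4]))
  y[seq(1L, 2L * d[1], 2L), seq(1L, 2L * d[2], 2L),
    seq(1L, 2L * d[3], 2L), ] <- x
  y
}

zstuff3_b <- function(dy, in_dim) {
  dy[seq(1L, 2L * in_dim[1], 2L), seq(1L, 2L * in_dim[2], 2L),
     seq(1L, 2L * in_dim[3], 2L), , drop = FALSE]
}

he_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
lin_init <- function(dims, fan_in) array(rnorm(prod(dims), 0, sqrt(1 / fan_in)), dims)

# Adam with bias correction; `state` carries m, v and the step counter
adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one Adam step, updating parameters and moments in place (C++); `grads`
# is realigned to the parameter order by name
adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  .adam_inplace(params, grads[names(params)], state$m, state$v,
                state$t, lr, beta1, beta2, eps)
  state
}

grads_add_inplace <- function(a, b) .axpy_inplace(a, b[names(a)], 1)

grads_scale_inplace <- function(a, s) .scale_inplace(a, s)
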
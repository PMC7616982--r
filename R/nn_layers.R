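# Minimal CPU neural-network primitives for the slice-stack regression
# network: 2D convolution (im2col + matrix multiply), ReLU, batch
# normalisation, 2x2 max pooling, 2x2 stride-2 transposed convolution,
# inverted dropout, and Adam. Activations are stored as matrices of shape
# (H*W*C) x N with rows ordered pixel-fastest then channel, so channel
# concatenation is row-binding.

new_conv <- function(cin, cout, k, h, w, rng) {
  fan_in <- k * k * cin
  list(type = "conv", k = k, cin = cin, cout = cout, h = h, w = w,
       W = matrix(rng(cout * fan_in) * sqrt(2 / fan_in), cout, fan_in),
       b = numeric(cout))
}

conv_forward <- function(layer, x) {
  y <- cpp_conv_forward(x, t(layer$W), layer$b, layer$h, layer$w,
                        layer$cin, layer$k)
  list(y = y, cache = x)
}

conv_backward <- function(layer, dy, cache, n) {
  g <- cpp_conv_backward(cache, dy, t(layer$W), layer$h, layer$w,
                         layer$cin, layer$k)
  list(dx = g$dx, dW = t(g$dWt), db = as.numeric(g$db))
}

relu_forward <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_backward <- function(dy, cache) dy * cache

new_batchnorm <- function(c, hw) {
  list(type = "bn", c = c, hw = hw,
       gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.1,
       eps = 1e-5)
}

bn_forward <- function(layer, x, training = TRUE) {
  hw <- layer$hw; cc <- layer$c; n <- ncol(x)
  if (training) {
    m2 <- matrix(.colSums(matrix(x, hw), hw, cc * n), cc, n)
    mu <- rowSums(m2) / (hw * n)
    v2 <- matrix(.colSums(matrix(x * x, hw), hw, cc * n), cc, n)
    varc <- rowSums(v2) / (hw * n) - mu^2
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * varc
  } else {
    mu <- layer$run_mean
    varc <- layer$run_var
  }
  sd_row <- rep(sqrt(varc + layer$eps), each = hw)
  mu_row <- rep(mu, each = hw)
  xhat <- (x - mu_row) / sd_row
  y <- xhat * rep(layer$gamma, each = hw) + rep(layer$beta, each = hw)
  list(y = y, cache = list(xhat = xhat, sd_row = sd_row), layer = layer)
}

bn_backward <- function(layer, dy, cache) {
  hw <- layer$hw; cc <- layer$c; n <- ncol(dy)
  M <- hw * n
  xhat <- cache$xhat
  sumc <- function(m) rowSums(matrix(.colSums(matrix(m, hw), hw, cc * n), cc, n))
  dgamma <- sumc(dy * xhat)
  dbeta <- sumc(dy)
  g_row <- rep(layer$gamma, each = hw)
  dxhat <- dy * g_row
  t1 <- rep(sumc(dxhat), each = hw)
  t2 <- xhat * rep(sumc(dxhat * xhat), each = hw)
  dx <- (dxhat - t1 / M - t2 / M) / cache$sd_row
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

new_maxpool <- function(h, w, cc) {
  h2 <- h %/% 2L; w2 <- w %/% 2L
  oi <- rep(seq_len(h2), w2 * cc)
  oj <- rep(rep(seq_len(w2), each = h2), cc)
  ch <- rep(seq_len(cc), each = h2 * w2)
  base <- function(di, dj) (2L * oi - 1L + di) + (2L * oj - 2L + dj) * h +
    (ch - 1L) * h * w
  list(type = "pool", h = h, w = w, c = cc,
       p = cbind(base(0L, 0L), base(1L, 0L), base(0L, 1L), base(1L, 1L)))
}

pool_forward <- function(layer, x) {
  n <- ncol(x)
  m <- nrow(layer$p)
  cand <- cbind(as.vector(x[layer$p[, 1], ]), as.vector(x[layer$p[, 2], ]),
                as.vector(x[layer$p[, 3], ]), as.vector(x[layer$p[, 4], ]))
  am <- max.col(cand, ties.method = "first")
  y <- matrix(cand[cbind(seq_len(m * n), am)], m, n)
  list(y = y, cache = am)
}

pool_backward <- function(layer, dy, cache, n) {
  m <- nrow(layer$p)
  rows <- layer$p[cbind(rep(seq_len(m), n), cache)]
  dx <- matrix(0, layer$h * layer$w * layer$c, n)
  dx[cbind(rows, rep(seq_len(n), each = m))] <- as.vector(dy)
  dx
}

new_convtranspose <- function(cin, cout, h, w, rng) {
  # 2x2 kernel, stride 2: a pure block-scatter; rows of W ordered
  # (offset within 2x2 block, then output channel)
  fan_in <- cin
  h2 <- 2L * h; w2 <- 2L * w
  offs <- expand.grid(di = 0:1, dj = 0:1)
  # output row for flattened (a, p): a = o + (co-1)*4, p pixel index
  oi <- rep(seq_len(h), w)
  oj <- rep(seq_len(w), each = h)
  P <- integer(4L * cout * h * w)
  for (p in seq_len(h * w)) {
    for (co in seq_len(cout)) {
      for (o in 1:4) {
        a <- o + (co - 1L) * 4L
        r <- a + (p - 1L) * 4L * cout
        P[r] <- (2L * oi[p] - 1L + offs$di[o]) +
          (2L * oj[p] - 2L + offs$dj[o]) * h2 + (co - 1L) * h2 * w2
      }
    }
  }
  list(type = "convt", cin = cin, cout = cout, h = h, w = w, P = P,
       W = matrix(rng(4 * cout * cin) * sqrt(2 / fan_in), 4 * cout, cin),
       b = numeric(cout))
}

convt_forward <- function(layer, x) {
  n <- ncol(x)
  hw <- layer$h * layer$w
  dim(x) <- c(hw, layer$cin, n)
  x <- aperm(x, c(2, 1, 3))
  dim(x) <- c(layer$cin, hw * n)
  y <- layer$W %*% x
  dim(y) <- c(4L * layer$cout * hw, n)
  out <- matrix(0, 4L * hw * layer$cout, n)
  out[layer$P, ] <- y
  out <- out + rep(layer$b, each = 4L * hw)
  list(y = out, cache = x)
}

convt_backward <- function(layer, dy, cache, n) {
  hw <- layer$h * layer$w
  db <- rowSums(matrix(.colSums(matrix(dy, 4L * hw), 4L * hw, layer$cout * n),
                       layer$cout, n))
  dyp <- dy[layer$P, , drop = FALSE]
  dim(dyp) <- c(4L * layer$cout, hw * n)
  dW <- tcrossprod(dyp, cache)
  dxm <- crossprod(layer$W, dyp)
  dim(dxm) <- c(layer$cin, hw, n)
  dxm <- aperm(dxm, c(2, 1, 3))
  dim(dxm) <- c(hw * layer$cin, n)
  list(dx = dxm, dW = dW, db = db)
}

dropout_forward <- function(x, p, training, rng_unif) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - p
  mask <- matrix(rng_unif(length(x)) < keep, nrow(x), ncol(x)) / keep
  list(y = x * mask, cache = mask)
}

dropout_backward <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}
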
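# Minimal convolutional-network primitives.
#
# Feature maps are 4-D arrays dim = c(h, w, channels, batch). Convolutions are
# evaluated as im2col gathers followed by one BLAS matrix multiply; backward
# passes are the standard hand-derived gradients. Everything is deterministic:
# no threading or atomics are involved beyond BLAS GEMM.

# Precompute the linear gather indices for an im2col patch matrix.
# Returns list(idx, oh, ow) where idx is an integer vector of length
# oh*ow*kh*kw*cin indexing into an (h, w, cin) array, ordered so that
# matrix(x[idx], nrow = oh*ow) has columns ordered (kh fastest, kw, cin) --
# matching a weight matrix of dim (kh*kw*cin, cout) built from an array
# dim c(kh, kw, cin, cout).
im2col_index <- function(h, w, cin, kh, kw, sh, sw) {
  oh <- (h - kh) %/% sh + 1L
  ow <- (w - kw) %/% sw + 1L
  stopifnot(oh >= 1, ow >= 1)
  pos0 <- as.vector(outer((0:(oh - 1)) * sh, (0:(ow - 1)) * sw * h, "+"))
  off0 <- as.vector(outer(0:(kh - 1), (0:(kw - 1)) * h, "+"))
  off0 <- as.vector(outer(off0, (0:(cin - 1)) * h * w, "+"))
  idx <- outer(pos0, off0, "+") + 1L
  list(idx = as.integer(idx), oh = oh, ow = ow, kh = kh, kw = kw,
       sh = sh, sw = sw)
}

pad_array <- function(x, pad) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

unpad_array <- function(x, pad, h, w) {
  if (pad == 0) return(x)
  x[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

# He-uniform initialisation for a (kh*kw*cin) x cout weight matrix.
conv_params <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  lim <- sqrt(6 / fan_in)
  list(W = matrix(stats::runif(fan_in * cout, -lim, lim), fan_in, cout),
       b = numeric(cout), kh = kh, kw = kw, cin = cin, cout = cout)
}

bn_params <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

bn_state <- function(c) {
  list(mean = numeric(c), var = rep(1, c))
}

conv_forward <- function(x, par, stride, pad, cache_needed = TRUE) {
  d <- dim(x)
  if (d[3] != par$cin) {
    stop(sprintf("channel mismatch: layer expects %d input channels, got %d",
                 par$cin, d[3]), call. = FALSE)
  }
  xp <- pad_array(x, pad)
  dp <- dim(xp)
  ix <- im2col_index(dp[1], dp[2], dp[3], par$kh, par$kw, stride, stride)
  n <- d[4]
  ohw <- ix$oh * ix$ow
  P <- matrix(0, n * ohw, par$kh * par$kw * par$cin)
  for (i in seq_len(n)) {
    xi <- xp[, , , i]
    P[(i - 1L) * ohw + seq_len(ohw), ] <- xi[ix$idx]
  }
  Y <- P %*% par$W
  Y <- sweep(Y, 2, par$b, "+")
  out <- array(0, c(ix$oh, ix$ow, par$cout, n))
  for (i in seq_len(n)) {
    out[, , , i] <- Y[(i - 1L) * ohw + seq_len(ohw), ]
  }
  cache <- if (cache_needed) {
    list(P = P, ix = ix, dims_in = d, pad = pad, stride = stride, par = par)
  }
  list(out = out, cache = cache)
}

conv_backward <- function(dout, cache) {
  ix <- cache$ix; par <- cache$par
  d <- cache$dims_in
  n <- d[4]
  ohw <- ix$oh * ix$ow
  dY <- matrix(0, n * ohw, par$cout)
  for (i in seq_len(n)) {
    dY[(i - 1L) * ohw + seq_len(ohw), ] <- dout[, , , i]
  }
  dW <- crossprod(cache$P, dY)
  db <- colSums(dY)
  dP <- tcrossprod(dY, par$W)
  hp <- d[1] + 2 * cache$pad
  wp <- d[2] + 2 * cache$pad
  dxp <- array(0, c(hp, wp, d[3], n))
  rows <- function(k, o, s) k + (0:(o - 1)) * s
  ccols <- seq_len(d[3])
  for (i in seq_len(n)) {
    blk <- (i - 1L) * ohw + seq_len(ohw)
    for (kj in seq_len(par$kw)) {
      for (ki in seq_len(par$kh)) {
        colsel <- ki + (kj - 1) * par$kh + (ccols - 1) * par$kh * par$kw
        dxp[rows(ki, ix$oh, cache$stride),
            rows(kj, ix$ow, cache$stride), , i] <-
          dxp[rows(ki, ix$oh, cache$stride),
              rows(kj, ix$ow, cache$stride), , i] +
          array(dP[blk, colsel], c(ix$oh, ix$ow, d[3]))
      }
    }
  }
  dx <- unpad_array(dxp, cache$pad, d[1], d[2])
  list(dx = dx, dW = dW, db = db)
}

maxpool_forward <- function(x, k, stride, cache_needed = TRUE) {
  d <- dim(x)
  ix <- im2col_index(d[1], d[2], 1L, k, k, stride, stride)
  n <- d[4]; cin <- d[3]
  ohw <- ix$oh * ix$ow
  out <- array(0, c(ix$oh, ix$ow, cin, n))
  amax <- if (cache_needed) matrix(0L, ohw * cin, n)
  for (i in seq_len(n)) {
    for (ch in seq_len(cin)) {
      plane <- x[, , ch, i]
      P <- matrix(plane[ix$idx], nrow = ohw)
      out[, , ch, i] <- do.call(pmax, as.data.frame(P))
      if (cache_needed) {
        amax[(ch - 1L) * ohw + seq_len(ohw), i] <- max.col(P, "first")
      }
    }
  }
  cache <- if (cache_needed) list(ix = ix, dims_in = d, k = k,
                                  stride = stride, amax = amax)
  list(out = out, cache = cache)
}

maxpool_backward <- function(dout, cache) {
  ix <- cache$ix; d <- cache$dims_in
  ohw <- ix$oh * ix$ow
  idxmat <- matrix(ix$idx, nrow = ohw)
  dx <- array(0, d)
  for (i in seq_len(d[4])) {
    for (ch in seq_len(d[3])) {
      sel <- idxmat[cbind(seq_len(ohw),
                          cache$amax[(ch - 1L) * ohw + seq_len(ohw), i])]
      g <- as.vector(dout[, , ch, i])
      plane <- numeric(d[1] * d[2])
      acc <- rowsum(g, sel)
      plane[as.integer(rownames(acc))] <- acc
      dx[, , ch, i] <- plane
    }
  }
  dx
}

# Channel-wise sums over (h, w, batch): returns length-c vector.
channel_stat <- function(x, f) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  f(m)
}

bn_forward <- function(x, par, st, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  cc <- d[3]
  if (training) {
    mu <- channel_stat(x, colMeans)
    v <- channel_stat(x, function(m) colMeans(m^2)) - mu^2
    v <- pmax(v, 0)
    st$mean <- (1 - momentum) * st$mean + momentum * mu
    ntot <- d[1] * d[2] * d[4]
    st$var <- (1 - momentum) * st$var +
      momentum * v * ntot / max(1, ntot - 1)
  } else {
    mu <- st$mean
    v <- st$var
  }
  invstd <- 1 / sqrt(v + eps)
  scale <- par$gamma * invstd
  shift <- par$beta - mu * scale
  bvec <- function(vals) rep(rep(vals, each = d[1] * d[2]), times = d[4])
  out <- x * bvec(scale) + bvec(shift)
  xhat <- if (training) x * bvec(invstd) - bvec(mu * invstd)
  cache <- if (training) list(xhat = xhat, invstd = invstd, par = par,
                              dims = d)
  list(out = out, state = st, cache = cache)
}

bn_backward <- function(dout, cache) {
  d <- cache$dims
  m <- d[1] * d[2] * d[4]
  bvec <- function(vals) rep(rep(vals, each = d[1] * d[2]), times = d[4])
  dgamma <- channel_stat(dout * cache$xhat, colSums)
  dbeta <- channel_stat(dout, colSums)
  dxhat <- dout * bvec(cache$par$gamma)
  s1 <- channel_stat(dxhat, colSums)
  s2 <- channel_stat(dxhat * cache$xhat, colSums)
  dx <- bvec(cache$invstd / m) *
    (m * dxhat - bvec(s1) - cache$xhat * bvec(s2))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_backward <- function(dout, mask) dout * mask

linear_params <- function(din, dout, scale = NULL) {
  lim <- scale %||% sqrt(6 / din)
  list(W = matrix(stats::runif(din * dout, -lim, lim), din, dout),
       b = numeric(dout))
}
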
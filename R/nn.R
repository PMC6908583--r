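# Minimal convolutional-network primitives used by the generator and
# discriminator. Convolutions are im2col gathers followed by BLAS matrix
# products; index matrices are memoised per (input shape, kernel, stride,
# pad) in a per-network cache environment, so the gather itself is a single
# vectorised subset.
#
# Conventions: activations are H x W x C arrays; weights of a k x k
# convolution with Cin inputs and Cout outputs are a (k*k*Cin) x Cout matrix
# whose rows are ordered (kr, kc, channel) fastest-to-slowest, matching the
# index builder below.

conv_index <- function(H, W, C, k, stride, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  r0 <- (seq_len(Ho) - 1L) * stride + 1L
  c0 <- (seq_len(Wo) - 1L) * stride + 1L
  base <- as.vector(outer(r0, (c0 - 1L) * Hp, "+"))        # Ho*Wo positions
  off <- as.vector(outer(0:(k - 1L),
                         as.vector(outer((0:(k - 1L)) * Hp,
                                         (0:(C - 1L)) * Hp * Wp, "+")), "+"))
  idx <- outer(base, off, "+")
  # sparse scatter matrix: col2im accumulation as one sparse matvec
  scat <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx),
                               x = 1, dims = c(Hp * Wp * C, length(idx)))
  list(idx = idx, scat = scat, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
       H = H, W = W, C = C, pad = pad)
}

get_conv_index <- function(cache, H, W, C, k, stride, pad) {
  key <- paste(H, W, C, k, stride, pad, sep = "_")
  ci <- cache[[key]]
  if (is.null(ci)) {
    ci <- conv_index(H, W, C, k, stride, pad)
    cache[[key]] <- ci
  }
  ci
}

pad_zero <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

conv_init <- function(k, cin, cout, stride = 1L, pad = 1L, init_sd = 0.02) {
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = init_sd),
                  nrow = k * k * cin, ncol = cout),
       b = numeric(cout),
       k = as.integer(k), cin = as.integer(cin), cout = as.integer(cout),
       stride = as.integer(stride), pad = as.integer(pad))
}

conv_fwd <- function(p, x, cache) {
  d <- dim(x)
  ci <- get_conv_index(cache, d[1], d[2], d[3], p$k, p$stride, p$pad)
  xp <- pad_zero(x, p$pad)
  cols <- xp[ci$idx]
  dim(cols) <- dim(ci$idx)
  y <- cols %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(ci$Ho, ci$Wo, p$cout)
  list(y = y, cols = cols, ci = ci)
}

conv_bwd <- function(p, fwd, dy) {
  ci <- fwd$ci
  dym <- matrix(dy, nrow = ci$Ho * ci$Wo, ncol = p$cout)
  dW <- crossprod(fwd$cols, dym)
  db <- colSums(dym)
  dcols <- tcrossprod(dym, p$W)
  dxp <- as.vector(ci$scat %*% as.vector(dcols))
  dim(dxp) <- c(ci$Hp, ci$Wp, ci$C)
  dx <- if (ci$pad > 0L)
    dxp[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), , drop = FALSE]
  else dxp
  list(dx = dx, dW = dW, db = db)
}

lrelu <- function(x, a = 0.2) {
  neg <- x < 0
  x[neg] <- a * x[neg]
  x
}
lrelu_grad <- function(x, dy, a = 0.2) {
  neg <- x < 0
  dy[neg] <- a * dy[neg]
  dy
}
relu <- function(x) pmax(x, 0)
relu_grad <- function(x, dy) dy * (x > 0)

upsample2 <- function(x) {
  d <- dim(x)
  x[ceiling(seq_len(2L * d[1]) / 2), ceiling(seq_len(2L * d[2]) / 2), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1L, d[1], by = 2L); e1 <- seq(2L, d[1], by = 2L)
  o2 <- seq(1L, d[2], by = 2L); e2 <- seq(2L, d[2], by = 2L)
  dy[o1, o2, , drop = FALSE] + dy[e1, o2, , drop = FALSE] +
    dy[o1, e2, , drop = FALSE] + dy[e1, e2, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

# ---- Adam ----------------------------------------------------------------

adam_state_conv <- function(layer) {
  list(W = list(m = layer$W * 0, v = layer$W * 0),
       b = list(m = layer$b * 0, v = layer$b * 0))
}

# Stable 2-way softmax over a length-2 logit vector.
softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
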
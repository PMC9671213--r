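# 1D neural-net layer primitives on (batch, length, channels) arrays.
# Convolutions use im2col so the inner product runs through BLAS; all
# backward passes return exact analytic gradients (checked against finite
# differences in the test suite).

# ---- conv1d: stride 1, same padding, odd kernel -----------------------------

conv1d_forward <- function(x, W, b) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, c(n, L + 2L * pad, C))
  xp[, pad + seq_len(L), ] <- x
  Xcol <- matrix(0, n * L, k * C)
  for (o in seq_len(k)) {
    Xcol[, ((o - 1L) * C + 1L):(o * C)] <-
      matrix(xp[, o:(o + L - 1L), , drop = FALSE], n * L, C)
  }
  Wm <- matrix(aperm(W, c(2, 1, 3)), k * C, Cout)
  Y <- Xcol %*% Wm + rep(b, each = n * L)
  list(out = array(Y, c(n, L, Cout)), Xcol = Xcol)
}

conv1d_backward <- function(dout, Xcol, W, in_dim) {
  n <- in_dim[1]; L <- in_dim[2]; C <- in_dim[3]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  dY <- matrix(dout, n * L, Cout)
  Wm <- matrix(aperm(W, c(2, 1, 3)), k * C, Cout)
  dWm <- crossprod(Xcol, dY)                       # (k*C, Cout)
  dW <- aperm(array(dWm, c(C, k, Cout)), c(2, 1, 3))
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, Wm)                      # (n*L, k*C)
  dxp <- array(0, c(n, L + 2L * pad, C))
  for (o in seq_len(k)) {
    dxp[, o:(o + L - 1L), ] <- dxp[, o:(o + L - 1L), , drop = FALSE] +
      array(dXcol[, ((o - 1L) * C + 1L):(o * C)], c(n, L, C))
  }
  list(dx = dxp[, pad + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

# ---- max pooling ------------------------------------------------------------

maxpool_forward <- function(x, factor) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  stopifnot(L %% factor == 0L)
  Lo <- L %/% factor
  base <- seq(1L, L, by = factor)
  out <- x[, base, , drop = FALSE]
  which_off <- array(1L, c(n, Lo, C))
  for (o in seq_len(factor - 1L)) {
    cand <- x[, base + o, , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    which_off[upd] <- o + 1L
  }
  list(out = out, which_off = which_off, in_dim = d)
}

maxpool_backward <- function(dout, cache, factor) {
  d <- cache$in_dim
  dx <- array(0, d)
  Lo <- d[2] %/% factor
  base <- seq(1L, d[2], by = factor)
  for (o in seq_len(factor)) {
    sel <- cache$which_off == o
    slab <- array(0, c(d[1], Lo, d[3]))
    slab[sel] <- dout[sel]
    dx[, base + o - 1L, ] <- slab
  }
  dx
}

# ---- nearest-neighbour upsampling -------------------------------------------

upsample_forward <- function(x, factor) {
  L <- dim(x)[2]
  x[, rep(seq_len(L), each = factor), , drop = FALSE]
}

upsample_backward <- function(dout, factor) {
  d <- dim(dout); Lo <- d[2] %/% factor
  dx <- array(0, c(d[1], Lo, d[3]))
  for (o in seq_len(factor)) {
    dx <- dx + dout[, seq(o, d[2], by = factor), , drop = FALSE]
  }
  dx
}

# ---- inverted dropout -------------------------------------------------------

dropout_forward <- function(x, rate) {
  keep <- array(runif(length(x)) >= rate, dim(x))
  list(out = x * keep / (1 - rate), keep = keep)
}

dropout_backward <- function(dout, keep, rate) {
  dout * keep / (1 - rate)
}

# ---- activations ------------------------------------------------------------

relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

# softmax over the channel dimension of an (n, L, C) array
softmax_channels <- function(z) {
  d <- dim(z)
  M <- matrix(z, d[1] * d[2], d[3])
  mx <- M[, 1L]
  for (j in seq_len(d[3])[-1L]) mx <- pmax(mx, M[, j])
  E <- exp(M - mx)
  P <- E / rowSums(E)
  array(P, d)
}
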
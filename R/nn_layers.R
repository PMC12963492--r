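# Layer primitives of the network engine. Activations are stored as
# column-major arrays (H, W, C, N); token matrices as (N_tok * N, d) with
# images stacked block-wise. Every layer has a forward returning
# list(out, cache) and a backward returning list(dx, <param grads>).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

## ---- parameter initialisation -------------------------------------------

init_conv <- function(k, cin, cout) {
  list(W = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 dim = c(k, k, cin, cout)),
       b = numeric(cout))
}

init_dense <- function(din, dout, gain = "he") {
  sd <- if (identical(gain, "he")) sqrt(2 / din) else sqrt(2 / (din + dout))
  list(W = matrix(stats::rnorm(din * dout, sd = sd), dout, din),
       b = numeric(dout))
}

init_bn <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C))
}

init_bn_buffers <- function(C) {
  list(running_mean = numeric(C), running_var = rep(1, C))
}

## ---- channel-indexed helpers --------------------------------------------
# x flattened as (HW, C, N); a vector of length C recycles correctly when
# expanded to length HW*C (R recycles it across the N blocks).

ch_expand <- function(v, HW) rep(v, each = HW)

ch_sums <- function(x, HW, C, N) {
  # per-channel, per-image sums -> C x N matrix
  cs <- colSums(matrix(x, HW, C * N))
  matrix(cs, C, N)
}

## ---- convolution (C++ kernels) ------------------------------------------

conv_forward <- function(x, p) {
  .conv2d_forward(x, p$W, p$b, dim(x), dim(p$W))
}

conv_backward <- function(x, p, dout, need_dx = TRUE) {
  .conv2d_backward(x, p$W, dout, dim(x), dim(p$W), need_dx)
}

## ---- batch normalization --------------------------------------------------

bn_forward <- function(x, p, buf, training) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- HW * N
  if (training) {
    s <- rowSums(ch_sums(x, HW, C, N))
    mu <- s / m
    xc <- x - ch_expand(mu, HW)
    v <- rowSums(ch_sums(xc * xc, HW, C, N)) / m
    inv <- 1 / sqrt(v + BN_EPS)
    xhat <- xc * ch_expand(inv, HW)
    out <- xhat * ch_expand(p$gamma, HW) + ch_expand(p$beta, HW)
    buf$running_mean <- (1 - BN_MOMENTUM) * buf$running_mean + BN_MOMENTUM * mu
    buf$running_var <- (1 - BN_MOMENTUM) * buf$running_var + BN_MOMENTUM * v
    list(out = out, cache = list(xhat = xhat, inv = inv, m = m, training = TRUE),
         buffers = buf)
  } else {
    inv <- 1 / sqrt(buf$running_var + BN_EPS)
    scale <- p$gamma * inv
    out <- x * ch_expand(scale, HW) +
      ch_expand(p$beta - buf$running_mean * scale, HW)
    list(out = out, cache = list(scale = scale, training = FALSE), buffers = buf)
  }
}

bn_backward <- function(p, cache, dout) {
  d <- dim(dout); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  if (!cache$training) {
    dx <- dout * ch_expand(cache$scale, HW)
    return(list(dx = dx, dgamma = numeric(C), dbeta = numeric(C)))
  }
  xhat <- cache$xhat; m <- cache$m
  dgamma <- rowSums(ch_sums(dout * xhat, HW, C, N))
  dbeta <- rowSums(ch_sums(dout, HW, C, N))
  dxhat <- dout * ch_expand(p$gamma, HW)
  # dx = inv/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- rowSums(ch_sums(dxhat, HW, C, N))
  s2 <- rowSums(ch_sums(dxhat * xhat, HW, C, N))
  dx <- (dxhat - ch_expand(s1 / m, HW) - xhat * ch_expand(s2 / m, HW)) *
    ch_expand(cache$inv, HW)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- elementwise ----------------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(mask, dout) dout * mask

## ---- squeeze-and-excitation ----------------------------------------------
# squeeze: spatial mean per channel; excitation: C -> C/r (ReLU) -> C
# (sigmoid); output: x rescaled channelwise by the gates.

init_se <- function(C, reduction = 16) {
  hidden <- max(1L, C %/% reduction)
  list(fc1 = init_dense(C, hidden, "he"), fc2 = init_dense(hidden, C, "glorot"))
}

se_forward <- function(x, p) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  s <- ch_sums(x, HW, C, N) / HW                        # C x N
  z1 <- p$fc1$W %*% s + p$fc1$b                          # hidden x N
  h1 <- z1 * (z1 > 0)
  z2 <- p$fc2$W %*% h1 + p$fc2$b                         # C x N
  g <- 1 / (1 + exp(-z2))
  out <- x * ch_expand(g, HW)                            # recycles over N? no:
  # ch_expand(g, HW) has length HW*C*N already (g is C x N), ordering matches
  dim(out) <- d
  list(out = out, cache = list(x = x, s = s, h1 = h1, g = g))
}

se_backward <- function(p, cache, dout) {
  d <- dim(dout); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  g <- cache$g
  dx <- dout * ch_expand(g, HW)
  dg <- ch_sums(dout * cache$x, HW, C, N)                # C x N
  dz2 <- dg * g * (1 - g)
  dW2 <- dz2 %*% t(cache$h1)
  db2 <- rowSums(dz2)
  dh1 <- t(p$fc2$W) %*% dz2
  dz1 <- dh1 * (cache$h1 > 0)
  dW1 <- dz1 %*% t(cache$s)
  db1 <- rowSums(dz1)
  ds <- t(p$fc1$W) %*% dz1                               # C x N
  dx <- dx + ch_expand(ds / HW, HW)
  dim(dx) <- d
  list(dx = dx, grads = list(fc1 = list(W = dW1, b = db1),
                             fc2 = list(W = dW2, b = db2)))
}

## ---- pooling ---------------------------------------------------------------

maxpool_forward <- function(x) {
  r <- .maxpool2_forward(x, dim(x))
  list(out = r$out, cache = list(idx = r$idx, xdim = dim(x)))
}

maxpool_backward <- function(cache, dout) {
  .maxpool2_backward(dout, cache$idx, cache$xdim)
}

## ---- tokenization ----------------------------------------------------------

#' Tokenize a feature map for attention
#'
#' Row-major flattening of an `(H, W, C, N)` feature map into an
#' `(H*W*N, C)` token matrix: the tokens of image `n` occupy rows
#' `(n-1)*H*W + 1 .. n*H*W`, and 1-based token `k` corresponds to pixel
#' `((k-1) %/% W + 1, (k-1) %% W + 1)`. [detokenize()] is its exact
#' inverse.
#'
#' @param x array `(H, W, C, N)` (or `(H, W, C)` for one image).
#' @return token matrix with attribute `"spatial"` recording the shape.
#' @export
tokenize <- function(x) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1L)
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  # row-major token order within an image: transpose spatial dims
  xt <- aperm(x, c(2, 1, 3, 4))            # (W, H, C, N)
  dim(xt) <- c(W * H, C, N)
  xt <- aperm(xt, c(1, 3, 2))              # (HW, N, C)
  tok <- matrix(xt, H * W * N, C)
  attr(tok, "spatial") <- c(H = H, W = W, C = C, N = N)
  tok
}

#' @rdname tokenize
#' @param tok token matrix from [tokenize()].
#' @param spatial the shape attribute (defaults to the one on `tok`).
#' @export
detokenize <- function(tok, spatial = attr(tok, "spatial")) {
  H <- spatial[["H"]]; W <- spatial[["W"]]; C <- spatial[["C"]]; N <- spatial[["N"]]
  xt <- array(tok, dim = c(W * H, N, C))
  xt <- aperm(xt, c(1, 3, 2))              # (WH, C, N)
  dim(xt) <- c(W, H, C, N)
  aperm(xt, c(2, 1, 3, 4))
}

## ---- multi-head self-attention --------------------------------------------

init_mhsa <- function(d_model) {
  list(Wq = init_dense(d_model, d_model, "glorot"),
       Wk = init_dense(d_model, d_model, "glorot"),
       Wv = init_dense(d_model, d_model, "glorot"),
       Wo = init_dense(d_model, d_model, "glorot"))
}

softmax_rows <- function(S) {
  S <- exp(S - apply(S, 1, max))
  S / rowSums(S)
}

#' Multi-head scaled dot-product self-attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` per head on a token sequence,
#' concatenates the heads and applies the output projection. All four
#' projections carry biases.
#'
#' @param tokens numeric matrix, `n_tokens x d_model`.
#' @param weights list with elements `Wq`, `Wk`, `Wv`, `Wo`, each a list of a
#'   `d_model x d_model` matrix `W` and a length-`d_model` bias `b` (as
#'   produced inside [build_lsetnet()]).
#' @param heads number of attention heads; must divide `d_model`.
#' @param return_attention if `TRUE`, attach the per-head attention matrices
#'   as attribute `"attention"`.
#' @return matrix of the same shape as `tokens`.
#' @export
mhsa <- function(tokens, weights, heads = 8, return_attention = FALSE) {
  r <- mhsa_forward(tokens, weights, heads,
                    n_images = 1L, keep_attention = return_attention)
  out <- r$out
  if (return_attention) attr(out, "attention") <- r$cache$A
  out
}

mhsa_forward <- function(tok, p, heads, n_images = 1L, keep_attention = TRUE) {
  M <- nrow(tok); d <- ncol(tok)
  stopifnot(d %% heads == 0)
  dk <- d %/% heads
  Tn <- M %/% n_images
  Q <- tok %*% t(p$Wq$W) + rep(p$Wq$b, each = M)
  K <- tok %*% t(p$Wk$W) + rep(p$Wk$b, each = M)
  V <- tok %*% t(p$Wv$W) + rep(p$Wv$b, each = M)
  Z <- matrix(0, M, d)
  A <- vector("list", n_images * heads)
  for (n in seq_len(n_images)) {
    rows <- ((n - 1) * Tn + 1):(n * Tn)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      S <- Q[rows, cols, drop = FALSE] %*% t(K[rows, cols, drop = FALSE]) / sqrt(dk)
      Ah <- softmax_rows(S)
      Z[rows, cols] <- Ah %*% V[rows, cols, drop = FALSE]
      A[[(n - 1) * heads + h]] <- Ah
    }
  }
  out <- Z %*% t(p$Wo$W) + rep(p$Wo$b, each = M)
  list(out = out,
       cache = list(tok = tok, Q = Q, K = K, V = V, Z = Z,
                    A = if (keep_attention) A else NULL,
                    heads = heads, dk = dk, Tn = Tn, n_images = n_images))
}

mhsa_backward <- function(p, cache, dout) {
  tok <- cache$tok; M <- nrow(tok); d <- ncol(tok)
  heads <- cache$heads; dk <- cache$dk; Tn <- cache$Tn
  dWo <- t(dout) %*% cache$Z
  dbo <- colSums(dout)
  dZ <- dout %*% p$Wo$W
  dQ <- matrix(0, M, d); dK <- matrix(0, M, d); dV <- matrix(0, M, d)
  for (n in seq_len(cache$n_images)) {
    rows <- ((n - 1) * Tn + 1):(n * Tn)
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * dk + 1):(h * dk)
      Ah <- cache$A[[(n - 1) * heads + h]]
      dZh <- dZ[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dAh <- dZh %*% t(Vh)
      dV[rows, cols] <- t(Ah) %*% dZh
      dS <- Ah * (dAh - rowSums(dAh * Ah))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dk)
      dK[rows, cols] <- t(dS) %*% cache$Q[rows, cols, drop = FALSE] / sqrt(dk)
    }
  }
  dtok <- dQ %*% p$Wq$W + dK %*% p$Wk$W + dV %*% p$Wv$W
  list(dx = dtok,
       grads = list(Wq = list(W = t(dQ) %*% tok, b = colSums(dQ)),
                    Wk = list(W = t(dK) %*% tok, b = colSums(dK)),
                    Wv = list(W = t(dV) %*% tok, b = colSums(dV)),
                    Wo = list(W = dWo, b = dbo)))
}

## ---- layer normalization ---------------------------------------------------

init_ln <- function(d) list(gamma = rep(1, d), beta = numeric(d))

ln_forward <- function(x, p) {
  # x: M x d, normalized per row
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * inv
  out <- xhat * rep(p$gamma, each = nrow(x)) + rep(p$beta, each = nrow(x))
  list(out = out, cache = list(xhat = xhat, inv = inv))
}

ln_backward <- function(p, cache, dout) {
  M <- nrow(dout); d <- ncol(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(p$gamma, each = M)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- dense -----------------------------------------------------------------
# x: din x N column layout

dense_forward <- function(x, p) {
  list(out = p$W %*% x + p$b, cache = x)
}

dense_backward <- function(p, x, dout) {
  list(dx = t(p$W) %*% dout,
       grads = list(W = dout %*% t(x), b = rowSums(dout)))
}

## ---- global average pooling ------------------------------------------------

#' Global average pooling
#'
#' Per-channel spatial mean of a feature map.
#'
#' @param x array `(H, W, C)` or `(H, W, C, N)`.
#' @return for a single map, a length-`C` vector; for a batch, a `C x N`
#'   matrix.
#' @export
gap <- function(x) {
  d <- dim(x)
  if (length(d) == 3) d <- c(d, 1L)
  dim(x) <- d
  g <- ch_sums(x, d[1] * d[2], d[3], d[4]) / (d[1] * d[2])
  if (d[4] == 1L) drop(g) else g
}

gap_backward <- function(dg, xdim) {
  HW <- xdim[1] * xdim[2]
  dx <- ch_expand(dg / HW, HW)
  dim(dx) <- xdim
  dx
}

## ---- softmax ---------------------------------------------------------------

softmax_cols <- function(z) {
  z <- exp(z - rep(apply(z, 2, max), each = nrow(z)))
  z / rep(colSums(z), each = nrow(z))
}
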
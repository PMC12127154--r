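## Minimal neural-network kernels. Data layout for temporal tensors is
## (channels, length, batch); convolutions are cross-correlations with zero
## "same" padding and stride 1, computed as im2col + GEMM. Every forward
## returns the cache its backward needs; parameters live in a flat named list
## so that optimizer state, counting and serialization stay trivial.

## ---- initializers ----------------------------------------------------------

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

glorot_init <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

## ---- conv1d ----------------------------------------------------------------

## x: (Cin, L, N); W: (Cout, Cin*k); b: (Cout). Zero "same" padding, stride 1.
## Heavy lifting is in the compiled per-sample im2col + GEMM kernel.
conv1d_forward <- function(x, W, b, k) {
  d <- dim(x)
  if (d[2L] < k)
    stop(sprintf("input length %d is shorter than kernel %d; need L >= %d",
                 d[2L], k, k), call. = FALSE)
  pl <- (k - 1L) %/% 2L
  y <- .conv1d_fwd_cpp(x, W, as.numeric(rep_len(b, nrow(W))), k, pl)
  list(y = y, cache = list(x = x, k = k, pl = pl))
}

conv1d_backward <- function(dy, W, cache) {
  out <- .conv1d_bwd_cpp(dy, cache$x, W, cache$k, cache$pl)
  list(dx = out$dx, dW = out$dW, db = as.numeric(out$db))
}

## ---- pooling as linear maps ------------------------------------------------

## adaptive average pooling matrix (Lin x Lout); bin o covers
## floor((o-1)*Lin/Lout) .. ceil(o*Lin/Lout) - 1 (0-based), as in standard
## adaptive pooling.
pool_matrix <- function(Lin, Lout) {
  P <- matrix(0, Lin, Lout)
  for (o in seq_len(Lout)) {
    a <- floor((o - 1L) * Lin / Lout) + 1L
    b <- ceiling(o * Lin / Lout)
    P[a:b, o] <- 1 / (b - a + 1L)
  }
  P
}

## x: (C, L, N) -> (C, Lout, N) adaptive average pooling. When Lout divides L
## this is non-overlapping strided averaging, done by reshaping (no GEMM);
## otherwise the dense pooling matrix is used.
pool_forward <- function(x, Lout) {
  d <- dim(x); C <- d[1L]; L <- d[2L]; N <- d[3L]
  if (L %% Lout == 0L) {
    s <- L %/% Lout
    y <- if (s == 1L) x else .avgpool_fwd_cpp(x, s)
    return(list(y = y, cache = list(stride = s, dims = d)))
  }
  P <- pool_matrix(L, Lout)
  xm <- matrix(aperm(x, c(2L, 1L, 3L)), L)
  ym <- crossprod(P, xm)
  y <- aperm(array(ym, c(Lout, C, N)), c(2L, 1L, 3L))
  list(y = y, cache = list(P = P, dims = d))
}

pool_backward <- function(dy, cache) {
  d <- cache$dims; C <- d[1L]; L <- d[2L]; N <- d[3L]
  if (!is.null(cache$stride)) {
    if (cache$stride == 1L) return(dy)
    return(.avgpool_bwd_cpp(dy, cache$stride))
  }
  Lout <- ncol(cache$P)
  dym <- matrix(aperm(dy, c(2L, 1L, 3L)), Lout)
  dxm <- cache$P %*% dym
  aperm(array(dxm, c(L, C, N)), c(2L, 1L, 3L))
}

## global average pool (C, L, N) -> (C, N)
gap_forward <- function(x) {
  d <- dim(x)
  y <- colMeans(aperm(x, c(2L, 1L, 3L)))   # means over L
  dim(y) <- c(d[1L], d[3L])
  list(y = y, cache = d)
}

gap_backward <- function(dy, dims) {
  C <- dims[1L]; L <- dims[2L]; N <- dims[3L]
  dx <- array(0, dims)
  scale <- dy / L
  for (l in seq_len(L)) dx[, l, ] <- scale
  dx
}

## ---- elementwise / dense ---------------------------------------------------

## cache is the OUTPUT y: the active set is y > 0
relu_forward <- function(x) {
  y <- .relu_fwd_cpp(x)
  list(y = y, cache = y)
}
relu_backward <- function(dy, y) .relu_bwd_cpp(dy, y)

## x: (Din, B); W: (Dout, Din)
linear_forward <- function(x, W, b) list(y = W %*% x + b, cache = x)
linear_backward <- function(dy, W, x) {
  list(dx = crossprod(W, dy), dW = dy %*% t(x), db = rowSums(dy))
}

## row-stable softmax over rows of a matrix (n x K): each ROW is a
## distribution
softmax_rows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

## softmax over columns (K x B): each COLUMN is a distribution
softmax_cols <- function(m) {
  m <- sweep(m, 2L, apply(m, 2L, max))
  e <- exp(m)
  sweep(e, 2L, colSums(e), "/")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- layer norm ------------------------------------------------------------

## normalizes each COLUMN of x (D x n) over its D features
layernorm_forward <- function(x, g, b, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  y <- xhat * g + b
  list(y = y, cache = list(xhat = xhat, istd = istd, g = g))
}

layernorm_backward <- function(dy, cache) {
  xhat <- cache$xhat; istd <- cache$istd; g <- cache$g
  dg <- rowSums(dy * xhat)
  db <- rowSums(dy)
  dxhat <- dy * g
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(sweep(dxhat, 2L, m1) - sweep(xhat, 2L, m2, "*"),
              2L, istd, "*")
  list(dx = dx, dg = dg, db = db)
}

## ---- multi-head self-attention over T tokens -------------------------------

## x: (D, T, B); params: Wq, Wk, Wv, Wo (D x D), bq, bk, bv, bo (D)
mha_forward <- function(x, p, n_heads) {
  d <- dim(x); D <- d[1L]; T <- d[2L]; B <- d[3L]
  dh <- D %/% n_heads
  xm <- x; dim(xm) <- c(D, T * B)
  Q <- p$Wq %*% xm + p$bq; dim(Q) <- c(D, T, B)
  K <- p$Wk %*% xm + p$bk; dim(K) <- c(D, T, B)
  V <- p$Wv %*% xm + p$bv; dim(V) <- c(D, T, B)
  scale <- 1 / sqrt(dh)
  A <- array(0, c(T, T, B, n_heads))      # attention weights
  O <- array(0, c(D, T, B))               # concatenated head outputs
  for (h in seq_len(n_heads)) {
    rows <- (h - 1L) * dh + seq_len(dh)
    for (i in seq_len(T)) {
      S <- matrix(0, B, T)
      for (j in seq_len(T))
        S[, j] <- colSums(Q[rows, i, , drop = FALSE] *
                          K[rows, j, , drop = FALSE]) * scale
      Ai <- softmax_rows(S)               # B x T
      A[i, , , h] <- t(Ai)
      acc <- matrix(0, dh, B)
      for (j in seq_len(T))
        acc <- acc + matrix(V[rows, j, ], dh, B) *
          rep(Ai[, j], each = dh)
      O[rows, i, ] <- acc
    }
  }
  om <- O; dim(om) <- c(D, T * B)
  y <- p$Wo %*% om + p$bo; dim(y) <- c(D, T, B)
  list(y = y, cache = list(x = x, Q = Q, K = K, V = V, A = A, O = O,
                           n_heads = n_heads, dh = dh))
}

mha_backward <- function(dy, p, cache) {
  x <- cache$x; d <- dim(x); D <- d[1L]; T <- d[2L]; B <- d[3L]
  n_heads <- cache$n_heads; dh <- cache$dh
  scale <- 1 / sqrt(dh)
  dym <- dy; dim(dym) <- c(D, T * B)
  om <- cache$O; dim(om) <- c(D, T * B)
  dWo <- dym %*% t(om)
  dbo <- rowSums(dym)
  dO <- crossprod(p$Wo, dym); dim(dO) <- c(D, T, B)
  dQ <- array(0, c(D, T, B)); dK <- array(0, c(D, T, B))
  dV <- array(0, c(D, T, B))
  for (h in seq_len(n_heads)) {
    rows <- (h - 1L) * dh + seq_len(dh)
    for (i in seq_len(T)) {
      dOi <- matrix(dO[rows, i, ], dh, B)
      Ai <- t(matrix(cache$A[i, , , h], T, B))      # B x T
      dA <- matrix(0, B, T)
      for (j in seq_len(T)) {
        Vj <- matrix(cache$V[rows, j, ], dh, B)
        dA[, j] <- colSums(dOi * Vj)
        dV[rows, j, ] <- matrix(dV[rows, j, ], dh, B) +
          dOi * rep(Ai[, j], each = dh)
      }
      dS <- Ai * (dA - rowSums(Ai * dA))            # softmax backward, B x T
      for (j in seq_len(T)) {
        Kj <- matrix(cache$K[rows, j, ], dh, B)
        Qi <- matrix(cache$Q[rows, i, ], dh, B)
        dQ[rows, i, ] <- matrix(dQ[rows, i, ], dh, B) +
          Kj * rep(dS[, j] * scale, each = dh)
        dK[rows, j, ] <- matrix(dK[rows, j, ], dh, B) +
          Qi * rep(dS[, j] * scale, each = dh)
      }
    }
  }
  xm <- x; dim(xm) <- c(D, T * B)
  dQm <- dQ; dim(dQm) <- c(D, T * B)
  dKm <- dK; dim(dKm) <- c(D, T * B)
  dVm <- dV; dim(dVm) <- c(D, T * B)
  dx <- crossprod(p$Wq, dQm) + crossprod(p$Wk, dKm) + crossprod(p$Wv, dVm)
  dim(dx) <- c(D, T, B)
  list(dx = dx,
       dWq = dQm %*% t(xm), dbq = rowSums(dQm),
       dWk = dKm %*% t(xm), dbk = rowSums(dKm),
       dWv = dVm %*% t(xm), dbv = rowSums(dVm),
       dWo = dWo, dbo = dbo)
}
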
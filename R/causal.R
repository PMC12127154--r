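## Confounder dictionary and the backdoor-adjusted classification head.
##
## The observable stand-in for the confounder C is a dictionary of per-class
## average feature vectors f_d(c) with empirical priors P(c). The head fuses a
## sample feature (query) with learnable key/value projections of the
## dictionary via scaled dot-product attention, passes the token sequence
## [f; fused; E_c[c]] through a single transformer encoder block and an MLP,
## and emits logits g; with the softmax link the output realizes the NWGM
## approximation of the backdoor adjustment,
## P(Z|do(X)) = sum_c P(Z|X,c) P(c) ~= Softmax(g(X, E_c[c])).

#' Build the confounder dictionary of per-class average features
#'
#' Entry c is the mean of the feature vectors of all samples whose label
#' vector is 1 at c (multi-label samples contribute to every positive class).
#' Priors are `counts / sum(counts)`. Classes with no samples get the global
#' feature mean as entry, a zero prior, and are flagged.
#'
#' @param features list (or `n x D` matrix) of D-dimensional feature vectors.
#' @param labels list (or `n x K` matrix) of 0/1 label vectors.
#' @return a `confounder_dictionary`: list with `entries` (K x D), `counts`,
#'   `priors`, `empty` (logical flags).
#' @export
build_dictionary <- function(features, labels) {
  Fm <- if (is.matrix(features)) features else do.call(rbind, features)
  Ym <- if (is.matrix(labels)) labels else do.call(rbind, labels)
  if (nrow(Fm) != nrow(Ym))
    stop("features and labels must have the same number of samples",
         call. = FALSE)
  K <- ncol(Ym); D <- ncol(Fm)
  counts <- colSums(Ym)
  ## sum over positive samples per class in one GEMM: (K x n) %*% (n x D)
  sums <- t(Ym) %*% Fm
  entries <- matrix(0, K, D)
  nonzero <- counts > 0
  entries[nonzero, ] <- sums[nonzero, , drop = FALSE] / counts[nonzero]
  if (any(!nonzero)) {
    warning(sum(!nonzero), " empty class(es); entries set to the global ",
            "feature mean", call. = FALSE)
    entries[!nonzero, ] <- matrix(colMeans(Fm), sum(!nonzero), D, byrow = TRUE)
  }
  priors <- if (sum(counts) > 0) counts / sum(counts) else rep(1 / K, K)
  structure(list(entries = entries, counts = as.numeric(counts),
                 priors = as.numeric(priors), empty = !nonzero),
            class = "confounder_dictionary")
}

#' Project dictionary entries into attention keys and values
#'
#' `K_c = W_k f_d(c) + b_k`, `V_c = W_v f_d(c) + b_v`, row-wise over the
#' dictionary.
#'
#' @param dict a [build_dictionary()] result.
#' @param params list with `W_k`, `W_v` (D x D) and `b_k`, `b_v` (length D).
#' @return list with `keys` and `values`, both K x D.
#' @export
project_kv <- function(dict, params) {
  stopifnot(inherits(dict, "confounder_dictionary"))
  D <- ncol(dict$entries)
  for (nm in c("W_k", "W_v"))
    if (!all(dim(params[[nm]]) == c(D, D)))
      stop("`", nm, "` must be ", D, " x ", D, call. = FALSE)
  list(keys = t(params$W_k %*% t(dict$entries) + params$b_k),
       values = t(params$W_v %*% t(dict$entries) + params$b_v))
}

#' Scaled dot-product attention fusion with the dictionary
#'
#' `weights = row-softmax(Q keys' / sqrt(D))`, `fused = weights %*% values`.
#'
#' @param Q query matrix, rows x D (one row per sample feature).
#' @param keys,values K x D matrices (projected dictionary).
#' @return list with `fused` (rows x D) and `weights` (rows x K; each row a
#'   distribution).
#' @export
attention_fuse <- function(Q, keys, values) {
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1L)
  if (nrow(keys) == 0L) stop("empty dictionary (K = 0)", call. = FALSE)
  D <- ncol(Q)
  if (ncol(keys) != D || ncol(values) != D)
    stop("Q, keys, values must share dimension D", call. = FALSE)
  W <- softmax_rows(Q %*% t(keys) / sqrt(D))
  list(fused = W %*% values, weights = W)
}

#' Weighted geometric mean of exp(g(x)) under a distribution (WGM)
#'
#' The unnormalized product form `prod_x exp(g(x))^{P(x)}`, evaluated
#' componentwise.
#'
#' @param g_values list of K-vectors g(x), one per support point.
#' @param probs distribution over support points.
#' @return K-vector.
#' @export
wgm_product <- function(g_values, probs) {
  check_distribution(probs)
  if (length(g_values) != length(probs))
    stop("`g_values` and `probs` lengths differ", call. = FALSE)
  out <- rep(1, length(g_values[[1L]]))
  for (i in seq_along(probs))
    out <- out * exp(g_values[[i]])^probs[i]
  out
}

#' NWGM approximation: softmax of the expected logits
#'
#' `NWGM[f] = Softmax(sum_x P(x) g(x))`, which equals the componentwise
#' normalization of the weighted geometric mean `prod_x exp(g(x))^{P(x)}`.
#'
#' @inheritParams wgm_product
#' @return K-vector summing to 1.
#' @export
nwgm_distribution <- function(g_values, probs) {
  check_distribution(probs)
  if (length(g_values) != length(probs))
    stop("`g_values` and `probs` lengths differ", call. = FALSE)
  eg <- Reduce(`+`, Map(function(g, p) p * g, g_values, as.list(probs)))
  as.numeric(softmax_cols(matrix(eg, ncol = 1L)))
}

check_distribution <- function(p, tol = 1e-9) {
  if (any(p < -tol) || abs(sum(p) - 1) > max(tol, 1e-6))
    stop("`probs` must be non-negative and sum to 1", call. = FALSE)
  invisible(p)
}

#' Expected confounder E_c[c] under the dictionary priors
#' @param dict a [build_dictionary()] result.
#' @return D-vector `sum_c P(c) entry(c)`.
#' @export
expected_confounder <- function(dict) {
  stopifnot(inherits(dict, "confounder_dictionary"))
  as.numeric(crossprod(dict$entries, dict$priors))
}

#' Exact backdoor mixture (testing oracle)
#'
#' `P(Z|do(X)) = sum_c P(Z|X,c) P(c)` evaluated exactly; used to bound the
#' NWGM approximation gap in tests.
#'
#' @param per_c_scores list of class-score distributions, one per dictionary
#'   entry (each sums to 1).
#' @param priors P(c) over entries.
#' @return K-vector (a distribution).
#' @export
backdoor_oracle <- function(per_c_scores, priors) {
  check_distribution(priors)
  for (s in per_c_scores) check_distribution(s, tol = 1e-6)
  Reduce(`+`, Map(function(s, p) p * s, per_c_scores, as.list(priors)))
}

## ---- causal branch (batched internals + single-sample surface) -------------

#' Initialize causal-branch parameters (one branch)
#' @param D feature dimension.
#' @param K_classes number of output classes.
#' @param ff_dim transformer feed-forward width.
#' @param use_cr include dictionary/attention/transformer parameters.
#' @param prefix name prefix, e.g. `"br1"`.
#' @param seed integer seed.
#' @return flat named list of parameter arrays.
#' @export
init_branch_params <- function(D, K_classes, ff_dim = 128L, use_cr = TRUE,
                               prefix = "br1", seed = 1L) {
  with_seed(seed, {
    p <- list()
    nm <- function(s) paste0(prefix, ".", s)
    if (use_cr) {
      p[[nm("proj.Wk")]] <- glorot_init(D, D); p[[nm("proj.bk")]] <- numeric(D)
      p[[nm("proj.Wv")]] <- glorot_init(D, D); p[[nm("proj.bv")]] <- numeric(D)
      for (s in c("Wq", "Wk", "Wv", "Wo"))
        p[[nm(paste0("mha.", s))]] <- glorot_init(D, D)
      for (s in c("bq", "bk", "bv", "bo"))
        p[[nm(paste0("mha.", s))]] <- numeric(D)
      p[[nm("ln1.g")]] <- rep(1, D); p[[nm("ln1.b")]] <- numeric(D)
      p[[nm("ff.W1")]] <- he_init(ff_dim, D, D); p[[nm("ff.b1")]] <- numeric(ff_dim)
      p[[nm("ff.W2")]] <- he_init(D, ff_dim, ff_dim); p[[nm("ff.b2")]] <- numeric(D)
      p[[nm("ln2.g")]] <- rep(1, D); p[[nm("ln2.b")]] <- numeric(D)
    }
    p[[nm("mlp.W1")]] <- he_init(D, D, D); p[[nm("mlp.b1")]] <- numeric(D)
    p[[nm("mlp.W2")]] <- he_init(D, D, D); p[[nm("mlp.b2")]] <- numeric(D)
    p[[nm("head.W")]] <- glorot_init(K_classes, D)
    p[[nm("head.b")]] <- numeric(K_classes)
    p
  })
}

## f: (D, B); returns logits (K_classes, B) + cache
branch_forward <- function(f, dict, params, prefix, n_heads = 4L,
                           use_cr = TRUE) {
  nm <- function(s) paste0(prefix, ".", s)
  D <- nrow(f); B <- ncol(f)
  cache <- list(use_cr = use_cr)
  if (use_cr) {
    if (is.null(dict))
      stop("no confounder dictionary: build or load one before the causal ",
           "branch", call. = FALSE)
    kv <- project_kv(dict, list(W_k = params[[nm("proj.Wk")]],
                                b_k = params[[nm("proj.bk")]],
                                W_v = params[[nm("proj.Wv")]],
                                b_v = params[[nm("proj.bv")]]))
    af <- attention_fuse(t(f), kv$keys, kv$values)
    fused <- t(af$fused)                      # (D, B)
    ec <- expected_confounder(dict)
    x <- array(0, c(D, 3L, B))
    x[, 1L, ] <- f
    x[, 2L, ] <- fused
    x[, 3L, ] <- ec
    ## pre-LN transformer encoder block: x + MHA(LN1(x)), then + FF(LN2(.))
    xm <- x; dim(xm) <- c(D, 3L * B)
    ln1 <- layernorm_forward(xm, params[[nm("ln1.g")]], params[[nm("ln1.b")]])
    xn <- ln1$y; dim(xn) <- c(D, 3L, B)
    mh <- mha_forward(xn, list(Wq = params[[nm("mha.Wq")]],
                               Wk = params[[nm("mha.Wk")]],
                               Wv = params[[nm("mha.Wv")]],
                               Wo = params[[nm("mha.Wo")]],
                               bq = params[[nm("mha.bq")]],
                               bk = params[[nm("mha.bk")]],
                               bv = params[[nm("mha.bv")]],
                               bo = params[[nm("mha.bo")]]), n_heads)
    mhy <- mh$y; dim(mhy) <- c(D, 3L * B)
    x1 <- xm + mhy
    ln2 <- layernorm_forward(x1, params[[nm("ln2.g")]], params[[nm("ln2.b")]])
    ff1 <- linear_forward(ln2$y, params[[nm("ff.W1")]], params[[nm("ff.b1")]])
    ffr <- relu_forward(ff1$y)
    ff2 <- linear_forward(ffr$y, params[[nm("ff.W2")]], params[[nm("ff.b2")]])
    tok <- x1 + ff2$y; dim(tok) <- c(D, 3L, B)
    u <- (tok[, 1L, ] + tok[, 2L, ] + tok[, 3L, ]) / 3
    u <- matrix(u, D, B)
    cache <- c(cache, list(dict = dict, f = f, weights = af$weights,
                           kv = kv, mha = mh$cache, ln1 = ln1$cache,
                           ff1 = ff1$cache, ffr = ffr$cache, ff2 = ff2$cache,
                           ln2 = ln2$cache, n_heads = n_heads, B = B, D = D))
  } else {
    u <- f
    cache <- c(cache, list(f = f, B = B, D = D))
  }
  m1 <- linear_forward(u, params[[nm("mlp.W1")]], params[[nm("mlp.b1")]])
  r1 <- relu_forward(m1$y)
  m2 <- linear_forward(r1$y, params[[nm("mlp.W2")]], params[[nm("mlp.b2")]])
  r2 <- relu_forward(m2$y)
  hd <- linear_forward(r2$y, params[[nm("head.W")]], params[[nm("head.b")]])
  cache <- c(cache, list(m1 = m1$cache, r1 = r1$cache, m2 = m2$cache,
                         r2 = r2$cache, hd = hd$cache))
  list(logits = hd$y, f_cau = r2$y, cache = cache)
}

branch_backward <- function(dlogits, params, prefix, cache) {
  nm <- function(s) paste0(prefix, ".", s)
  g <- list()
  hb <- linear_backward(dlogits, params[[nm("head.W")]], cache$hd)
  g[[nm("head.W")]] <- hb$dW; g[[nm("head.b")]] <- hb$db
  d2 <- relu_backward(hb$dx, cache$r2)
  mb2 <- linear_backward(d2, params[[nm("mlp.W2")]], cache$m2)
  g[[nm("mlp.W2")]] <- mb2$dW; g[[nm("mlp.b2")]] <- mb2$db
  d1 <- relu_backward(mb2$dx, cache$r1)
  mb1 <- linear_backward(d1, params[[nm("mlp.W1")]], cache$m1)
  g[[nm("mlp.W1")]] <- mb1$dW; g[[nm("mlp.b1")]] <- mb1$db
  du <- mb1$dx                                    # (D, B)
  if (!cache$use_cr)
    return(list(df = du, grads = g))
  D <- cache$D; B <- cache$B
  ## token mean backward, then pre-LN block in reverse
  dtok <- array(0, c(D, 3L, B))
  for (t in 1:3) dtok[, t, ] <- du / 3
  dtokm <- dtok; dim(dtokm) <- c(D, 3L * B)
  fb2 <- linear_backward(dtokm, params[[nm("ff.W2")]], cache$ff2)
  g[[nm("ff.W2")]] <- fb2$dW; g[[nm("ff.b2")]] <- fb2$db
  dfr <- relu_backward(fb2$dx, cache$ffr)
  fb1 <- linear_backward(dfr, params[[nm("ff.W1")]], cache$ff1)
  g[[nm("ff.W1")]] <- fb1$dW; g[[nm("ff.b1")]] <- fb1$db
  lb2 <- layernorm_backward(fb1$dx, cache$ln2)
  g[[nm("ln2.g")]] <- lb2$dg; g[[nm("ln2.b")]] <- lb2$db
  dx1 <- dtokm + lb2$dx                           # residual around FF
  dx1a <- dx1; dim(dx1a) <- c(D, 3L, B)
  mhb <- mha_backward(dx1a, list(Wq = params[[nm("mha.Wq")]],
                                 Wk = params[[nm("mha.Wk")]],
                                 Wv = params[[nm("mha.Wv")]],
                                 Wo = params[[nm("mha.Wo")]]), cache$mha)
  g[[nm("mha.Wq")]] <- mhb$dWq; g[[nm("mha.bq")]] <- mhb$dbq
  g[[nm("mha.Wk")]] <- mhb$dWk; g[[nm("mha.bk")]] <- mhb$dbk
  g[[nm("mha.Wv")]] <- mhb$dWv; g[[nm("mha.bv")]] <- mhb$dbv
  g[[nm("mha.Wo")]] <- mhb$dWo; g[[nm("mha.bo")]] <- mhb$dbo
  dmh <- mhb$dx; dim(dmh) <- c(D, 3L * B)
  lb1 <- layernorm_backward(dmh, cache$ln1)
  g[[nm("ln1.g")]] <- lb1$dg; g[[nm("ln1.b")]] <- lb1$db
  dx0 <- dx1 + lb1$dx                             # residual around MHA
  dim(dx0) <- c(D, 3L, B)
  df <- matrix(dx0[, 1L, ], D, B)
  dfused <- matrix(dx0[, 2L, ], D, B)             # (D, B)
  ## attention fusion backward: fused' = W %*% values (per sample row)
  Wt <- cache$weights                             # (B, K)
  Kd <- nrow(cache$dict$entries)
  dF <- t(dfused)                                 # (B, D)
  dvalues <- t(Wt) %*% dF                         # (K, D)
  dWt <- dF %*% t(cache$kv$values)                # (B, K)
  dS <- Wt * (dWt - rowSums(Wt * dWt))            # softmax backward
  scaleD <- 1 / sqrt(D)
  dQ <- (dS %*% cache$kv$keys) * scaleD           # (B, D), query = t(f)
  dkeys <- t(dS) %*% t(cache$f) * scaleD          # (K, D)
  df <- df + t(dQ)
  ## key/value projections: keys = entries %*% t(Wk) + bk
  E <- cache$dict$entries                         # (K, D)
  g[[nm("proj.Wk")]] <- t(dkeys) %*% E
  g[[nm("proj.bk")]] <- colSums(dkeys)
  g[[nm("proj.Wv")]] <- t(dvalues) %*% E
  g[[nm("proj.bv")]] <- colSums(dvalues)
  list(df = df, grads = g)
}

#' Run one feature vector through a causal branch
#'
#' Fuses the feature with the projected dictionary by attention, passes the
#' token sequence `[f; fused; E_c[c]]` through one transformer encoder block
#' and an MLP, and emits logits `g` and scores. With the softmax link the
#' scores realize `P(Z|do(X)) = Softmax(g(X, E_c[c]))`.
#'
#' @param f length-D feature vector (`f_upper` or `f_lower`).
#' @param dict a [build_dictionary()] result.
#' @param params branch parameters from [init_branch_params()].
#' @param prefix parameter name prefix (default `"br1"`).
#' @param link `"softmax"` or `"sigmoid"`.
#' @param n_heads attention heads in the transformer block.
#' @param use_cr set `FALSE` to bypass the causal-reasoning module
#'   (plain MLP head).
#' @return a `causal_branch_output`: list with `f_cau`, `logits`, `scores`,
#'   `attention` (the fusion weights, `NULL` when `use_cr = FALSE`).
#' @export
causal_branch <- function(f, dict, params, prefix = "br1",
                          link = c("softmax", "sigmoid"), n_heads = 4L,
                          use_cr = TRUE) {
  link <- match.arg(link)
  fm <- matrix(as.numeric(f), ncol = 1L)
  out <- branch_forward(fm, dict, params, prefix, n_heads = n_heads,
                        use_cr = use_cr)
  logits <- as.numeric(out$logits)
  scores <- if (link == "softmax")
    as.numeric(softmax_cols(out$logits)) else sigmoid(logits)
  structure(list(f_cau = as.numeric(out$f_cau), logits = logits,
                 scores = scores,
                 attention = if (use_cr) out$cache$weights else NULL),
            class = "causal_branch_output")
}
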
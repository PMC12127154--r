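## Shared fixtures and independent brute-force oracles. Oracles deliberately
## use naive loops so they share no code with the implementation they check.

## small synthetic population: 4 leads, 4 s at 50 Hz -> L = 200
tiny_synth_config <- function(seed = 1L, rho = 0.8) {
  synth_config(n_leads = 4L, duration = 4, fs = 50,
               confounder = confounder_spec(rho = rho),
               lead_projection = c(0.6, 0.9, 1.2, 1.5), seed = seed)
}

tiny_scheme <- function() view_scheme("custom", list(1:2, 3:4))

tiny_model_config <- function(...) {
  model_config(n_leads = 4L, scheme = tiny_scheme(), K_classes = 4L,
               encoder = encoder_config(conv_channels = c(4L, 8L),
                                        conv_kernel = 5L, pool1_stride = 4L,
                                        pooled_length = 50L,
                                        kernel_upper = 3L, kernel_lower = 20L,
                                        tdfe_channels = 8L, feat_dim = 16L),
               n_heads = 2L, ff_dim = 32L, ...)
}

## naive sliding-dot-product 1-D convolution ("same" zero padding),
## x: (Cin, L); W: (Cout, Cin*k) tap-major as in the package
oracle_conv1d <- function(x, W, b, k) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  Cin <- nrow(x); L <- ncol(x); Cout <- nrow(W)
  pl <- (k - 1) %/% 2
  y <- matrix(0, Cout, L)
  for (co in seq_len(Cout)) {
    for (t in seq_len(L)) {
      acc <- b[co]
      for (j in seq_len(k)) {
        s <- t + j - 1 - pl
        if (s >= 1 && s <= L)
          for (ci in seq_len(Cin))
            acc <- acc + W[co, (j - 1) * Cin + ci] * x[ci, s]
      }
      y[co, t] <- acc
    }
  }
  y
}

## exhaustive pairwise concordance AUC with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

## per-class means by re-walking the label matrix sample by sample
oracle_dictionary_entries <- function(features, labels) {
  K <- ncol(labels); D <- ncol(features)
  out <- matrix(NA_real_, K, D)
  for (c in seq_len(K)) {
    hit <- which(labels[, c] == 1)
    if (length(hit) > 0) out[c, ] <- colMeans(features[hit, , drop = FALSE])
  }
  out
}

## exact backdoor mixture by double loop over entries and classes
oracle_backdoor <- function(per_c_scores, priors) {
  K <- length(per_c_scores[[1]])
  out <- numeric(K)
  for (ci in seq_along(priors))
    for (k in seq_len(K))
      out[k] <- out[k] + per_c_scores[[ci]][k] * priors[ci]
  out
}

## find R-peak sample indices in a clean single-lead beat train
find_r_peaks <- function(sig, min_height = 0.5) {
  n <- length(sig)
  which(vapply(seq_len(n), function(i) {
    lo <- max(1, i - 5); hi <- min(n, i + 5)
    sig[i] >= max(sig[lo:hi]) && sig[i] > min_height * max(sig)
  }, logical(1)))
}

## collapse runs of adjacent indices (plateaus) to one peak each
collapse_peaks <- function(idx) {
  if (length(idx) == 0) return(idx)
  keep <- c(TRUE, diff(idx) > 5)
  idx[keep]
}
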
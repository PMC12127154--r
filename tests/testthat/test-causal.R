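test_that("dictionary entries are exact per-class feature means", {
  ## two samples of class A at (1,0) and (3,0) average to (2,0)
  f <- rbind(c(1, 0), c(3, 0), c(5, 5))
  y <- rbind(c(1, 0), c(1, 0), c(0, 1))
  d <- build_dictionary(f, y)
  expect_equal(d$entries[1, ], c(2, 0))
  ## a single-sample class equals that sample exactly
  expect_equal(d$entries[2, ], c(5, 5))
  expect_equal(d$counts, c(2, 1))
  expect_equal(d$priors, c(2 / 3, 1 / 3))
})

test_that("multi-label samples enter every positive class mean", {
  set.seed(12)
  f <- matrix(rnorm(40), 10, 4)
  y <- matrix(rbinom(30, 1, 0.4), 10, 3)
  y[1, ] <- c(1, 1, 0)                     # explicitly doubly-labeled
  y[2, ] <- 1                              # ensure no empty class
  y[3, ] <- c(0, 1, 1)
  d <- build_dictionary(f, y)
  ref <- oracle_dictionary_entries(f, y)
  for (c in 1:3)
    if (!any(is.na(ref[c, ]))) expect_equal(d$entries[c, ], ref[c, ])
  ## permutation invariance in sample order
  p <- sample(10)
  d2 <- build_dictionary(f[p, ], y[p, ])
  expect_equal(d2$entries, d$entries)
  expect_equal(d2$priors, d$priors)
})

test_that("empty classes fall back to the global mean with zero prior", {
  f <- rbind(c(1, 1), c(3, 3))
  y <- rbind(c(1, 0), c(1, 0))
  expect_warning(d <- build_dictionary(f, y), "empty class")
  expect_equal(d$entries[2, ], c(2, 2))    # global feature mean
  expect_equal(d$priors, c(1, 0))
  expect_true(d$empty[2])
})

test_that("key/value projections are exact row-wise affine maps", {
  set.seed(3)
  f <- matrix(rnorm(12), 3, 4); y <- diag(3)[, c(1, 2, 3)]
  d <- build_dictionary(f, y)
  D <- 4L
  ## identity projection returns the entries themselves
  idp <- list(W_k = diag(D), b_k = numeric(D), W_v = diag(D),
              b_v = numeric(D))
  kv <- project_kv(d, idp)
  expect_equal(kv$keys, d$entries)
  expect_equal(kv$values, d$entries)
  ## zero entries: keys are broadcast bias rows
  d0 <- d; d0$entries <- matrix(0, 3, 4)
  bk <- rnorm(4)
  kv0 <- project_kv(d0, list(W_k = diag(D), b_k = bk, W_v = diag(D),
                             b_v = numeric(D)))
  expect_equal(kv0$keys, matrix(bk, 3, 4, byrow = TRUE))
  ## random projection vs explicit per-row matrix-vector loop
  pr <- list(W_k = matrix(rnorm(16), 4), b_k = rnorm(4),
             W_v = matrix(rnorm(16), 4), b_v = rnorm(4))
  kvr <- project_kv(d, pr)
  for (c in 1:3) {
    expect_equal(kvr$keys[c, ],
                 as.numeric(pr$W_k %*% d$entries[c, ] + pr$b_k))
    expect_equal(kvr$values[c, ],
                 as.numeric(pr$W_v %*% d$entries[c, ] + pr$b_v))
  }
  expect_error(project_kv(d, list(W_k = diag(3), b_k = numeric(3),
                                  W_v = diag(3), b_v = numeric(3))), "4 x 4")
})

test_that("attention fusion is a softmax-weighted dictionary average", {
  set.seed(5)
  D <- 6L
  Q <- matrix(rnorm(3 * D), 3)
  ## K = 1: fused equals the single value row for any query
  k1 <- matrix(rnorm(D), 1); v1 <- matrix(rnorm(D), 1)
  af1 <- attention_fuse(Q, k1, v1)
  for (r in 1:3) expect_equal(af1$fused[r, ], v1[1, ])
  expect_equal(af1$weights, matrix(1, 3, 1))
  ## identical keys: fused = unweighted mean of values
  keys <- matrix(rep(rnorm(D), 4), 4, byrow = TRUE)
  vals <- matrix(rnorm(4 * D), 4)
  af2 <- attention_fuse(Q, keys, vals)
  for (r in 1:3) expect_equal(af2$fused[r, ], colMeans(vals))
  ## weights are row-stochastic and non-negative
  af3 <- attention_fuse(Q, matrix(rnorm(4 * D), 4), vals)
  expect_true(all(af3$weights >= 0))
  expect_equal(rowSums(af3$weights), rep(1, 3), tolerance = 1e-6)
  expect_error(attention_fuse(Q, matrix(numeric(0), 0, D), vals), "empty")
})

test_that("NWGM softmax-of-expectation equals the normalized WGM product", {
  ## degenerate distributions
  g <- list(c(0.3, -1, 2))
  expect_equal(nwgm_distribution(g, 1),
               exp(g[[1]]) / sum(exp(g[[1]])))
  g2 <- list(c(1, 2), c(-5, 7))
  expect_equal(nwgm_distribution(g2, c(1, 0)),
               exp(g2[[1]]) / sum(exp(g2[[1]])))
  ## identity on random instances (support 3, K = 4)
  set.seed(8)
  for (rep in 1:20) {
    gs <- lapply(1:3, function(i) rnorm(4))
    p <- runif(3); p <- p / sum(p)
    wgm <- wgm_product(gs, p)
    expect_equal(nwgm_distribution(gs, p), wgm / sum(wgm),
                 tolerance = 1e-10)
  }
  expect_error(nwgm_distribution(g2, c(0.5, 0.2)), "sum to 1")
})

test_that("expected confounder is the prior-weighted entry average", {
  f <- rbind(c(1, 0), c(3, 0))
  d <- build_dictionary(f, diag(2))
  expect_equal(expected_confounder(d), c(2, 0))      # uniform priors
  d$priors <- c(1, 0)
  expect_equal(expected_confounder(d), c(1, 0))      # degenerate prior
  ## convex-hull containment, componentwise
  set.seed(2)
  d$entries <- matrix(rnorm(10), 5); d$priors <- runif(5)
  d$priors <- d$priors / sum(d$priors)
  ec <- expected_confounder(d)
  for (j in 1:2) {
    expect_gte(ec[j], min(d$entries[, j]))
    expect_lte(ec[j], max(d$entries[, j]))
  }
})

test_that("backdoor mixture matches a brute-force double loop", {
  expect_equal(backdoor_oracle(list(c(0.2, 0.8), c(0.2, 0.8)), c(0.3, 0.7)),
               c(0.2, 0.8))
  expect_equal(backdoor_oracle(list(c(1, 0), c(0, 1)), c(0.5, 0.5)),
               c(0.5, 0.5))
  set.seed(10)
  for (rep in 1:10) {
    per <- lapply(1:4, function(i) { p <- runif(3); p / sum(p) })
    pr <- runif(4); pr <- pr / sum(pr)
    expect_equal(backdoor_oracle(per, pr), oracle_backdoor(per, pr))
  }
  expect_error(backdoor_oracle(list(c(0.9, 0.3)), 1), "sum to 1")
})

test_that("a linear interventional head is exactly the NWGM over entries", {
  ## for g(X, c) = A X + B c, Softmax(A X + B E_c[c]) must equal the NWGM
  ## of {g(X, entry_c)} under the priors, because expectation commutes with
  ## linear maps
  set.seed(11)
  D <- 5L; K <- 4L; Kd <- 6L
  A <- matrix(rnorm(K * D), K); B <- matrix(rnorm(K * D), K)
  f <- matrix(rnorm(Kd * D), Kd)
  y <- matrix(0, Kd, Kd); y[cbind(1:Kd, 1:Kd)] <- 1
  d <- build_dictionary(f, y)
  d$priors <- runif(Kd); d$priors <- d$priors / sum(d$priors)
  x <- rnorm(D)
  lhs <- as.numeric(causalecg:::softmax_cols(
    matrix(A %*% x + B %*% expected_confounder(d), ncol = 1)))
  gs <- lapply(seq_len(Kd), function(c)
    as.numeric(A %*% x + B %*% d$entries[c, ]))
  rhs <- nwgm_distribution(gs, d$priors)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("causal_branch degenerates correctly and yields distributions", {
  set.seed(13)
  D <- 16L; K <- 4L
  params <- init_branch_params(D, K, ff_dim = 32L, prefix = "br1", seed = 1)
  f <- rnorm(D)
  feats <- matrix(rnorm(8 * D), 8)
  labs <- matrix(0, 8, K); labs[cbind(1:8, rep(1:4, 2))] <- 1
  d <- build_dictionary(feats, labs)
  out <- causal_branch(f, d, params, link = "softmax", n_heads = 2L)
  expect_s3_class(out, "causal_branch_output")
  expect_equal(sum(out$scores), 1, tolerance = 1e-6)
  expect_equal(rowSums(out$attention), 1, tolerance = 1e-6)
  ## K = 1 dictionary: fused is that entry for any query (weights are 1)
  d1 <- build_dictionary(feats[1:2, ], matrix(1, 2, 1))
  kv <- project_kv(d1, list(W_k = diag(D), b_k = numeric(D),
                            W_v = diag(D), b_v = numeric(D)))
  af <- attention_fuse(matrix(f, 1), kv$keys, kv$values)
  expect_equal(af$fused[1, ], d1$entries[1, ])
  ## all-zero parameters: logits 0, softmax scores uniform 1/K
  z <- lapply(params, function(p) p * 0)
  names(z) <- names(params)
  outz <- causal_branch(f, d, z, link = "softmax", n_heads = 2L)
  expect_equal(outz$scores, rep(1 / K, K), tolerance = 1e-12)
  ## a missing dictionary is an actionable error
  expect_error(causal_branch(f, NULL, params), "build or load")
})
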
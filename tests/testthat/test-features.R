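test_that("1-D convolution agrees with a sliding dot-product oracle", {
  set.seed(4)
  for (dims in list(c(2L, 30L, 3L, 5L), c(3L, 25L, 4L, 4L),
                    c(1L, 40L, 2L, 8L))) {
    Cin <- dims[1]; L <- dims[2]; Cout <- dims[3]; k <- dims[4]
    x <- array(rnorm(Cin * L * 2), c(Cin, L, 2L))
    W <- matrix(rnorm(Cout * Cin * k), Cout)
    b <- rnorm(Cout)
    got <- causalecg:::conv1d_forward(x, W, b, k)$y
    for (n in 1:2)
      expect_equal(got[, , n], oracle_conv1d(x[, , n], W, b, k),
                   tolerance = 1e-5)
  }
})

test_that("identity kernel and zero input behave as linear algebra dictates", {
  ## kernel [1] with weight 1, bias 0 reproduces the input row exactly
  x <- array(rnorm(30), c(1L, 30L, 1L))
  got <- causalecg:::conv1d_forward(x, matrix(1, 1, 1), 0, 1L)$y
  expect_equal(got, x, tolerance = 0)
  ## zero input with zero biases stays zero through the whole encoder
  cfg <- tiny_model_config()
  params <- init_encoder_params(cfg$encoder, n_v = 2L, seed = 1)
  for (nm in grep("\\.b$", names(params), value = TRUE))
    params[[nm]] <- params[[nm]] * 0
  fmap <- encode_view(matrix(0, 2, 200), cfg$encoder, params)
  expect_true(all(fmap$values == 0))
  expect_identical(dim(fmap$values), c(8L, 50L))
  tout <- tdfe(fmap, cfg$encoder, params)
  expect_identical(tout$f_upper, rep(0, 16))
  expect_identical(tout$f_lower, rep(0, 16))
})

test_that("the fused encoder path equals the generic layer-by-layer path", {
  cfg <- tiny_model_config()
  params <- init_encoder_params(cfg$encoder, n_v = 2L, seed = 2)
  x <- array(rnorm(2 * 200 * 6), c(2L, 200L, 6L))
  fast <- causalecg:::encoder_forward(x, params, cfg$encoder)
  expect_true(isTRUE(fast$cache$fused))
  ## generic path: odd length disables the fused kernel, so pad config
  slow <- causalecg:::encoder_generic_forward(x, params, cfg$encoder)
  expect_equal(fast$y, slow$y, tolerance = 1e-10)
})

test_that("view aggregation is the exact element-wise mean", {
  set.seed(9)
  maps <- lapply(1:5, function(i)
    structure(list(values = matrix(rnorm(12), 3), view_index = i),
              class = "feature_map"))
  agg <- aggregate_views(maps)
  ref <- matrix(0, 3, 4)
  for (m in maps) ref <- ref + m$values
  expect_equal(agg$values, ref / 5, tolerance = 0)
  ## idempotent on identical maps; zero for v and -v
  expect_equal(aggregate_views(list(maps[[1]], maps[[1]]))$values,
               maps[[1]]$values)
  neg <- maps[[1]]; neg$values <- -neg$values
  expect_equal(aggregate_views(list(maps[[1]], neg))$values,
               matrix(0, 3, 4))
  bad <- maps[[1]]; bad$values <- matrix(0, 2, 4)
  expect_error(aggregate_views(list(maps[[1]], bad)), "shape")
})

test_that("TDFE responds to a constant input like an averaging filter", {
  cfg <- tiny_model_config()$encoder
  ## sum-1 averaging kernel, identity-friendly: constant positive input c
  ## keeps interior activations at c (zero padding perturbs only edges)
  k <- 5L; C <- 3L
  W <- matrix(0, C, C * k)
  for (ci in seq_len(C)) for (j in seq_len(k)) W[ci, (j - 1) * C + ci] <- 1 / k
  x <- array(2.5, c(C, 40L, 1L))
  y <- causalecg:::conv1d_forward(x, W, numeric(C), k)$y
  interior <- y[, 3:38, 1]
  expect_equal(interior, matrix(2.5, C, 36), tolerance = 1e-12)
  ## the ablation-grid kernel pair (40, 20) is expressible and finite
  cfg2 <- encoder_config(conv_channels = c(4L, 8L), conv_kernel = 5L,
                         pool1_stride = 4L, pooled_length = 50L,
                         kernel_upper = 40L, kernel_lower = 20L,
                         tdfe_channels = 8L, feat_dim = 16L)
  params <- init_encoder_params(cfg2, n_v = 2L, seed = 3)
  fmap <- encode_view(matrix(rnorm(2 * 200), 2, 200), cfg2, params)
  tout <- tdfe(fmap, cfg2, params)
  expect_length(tout$f_upper, 16L)
  expect_length(tout$f_lower, 16L)
  expect_true(all(is.finite(c(tout$f_upper, tout$f_lower))))
  ## remaining grid rows are constructible
  for (pair in list(c(40L, 10L), c(50L, 20L), c(50L, 10L)))
    expect_s3_class(encoder_config(kernel_upper = pair[1],
                                   kernel_lower = pair[2],
                                   pooled_length = 125L), "encoder_config")
})

test_that("kernel-size contracts are enforced with actionable errors", {
  expect_error(encoder_config(pooled_length = 30L, kernel_lower = 50L),
               "smaller")
  cfg <- tiny_model_config()$encoder
  params <- init_encoder_params(cfg, n_v = 2L, seed = 1)
  expect_error(encode_view(matrix(0, 2, 3), cfg, params), "shorter than")
})

test_that("pre-pooling activations respect the convolution receptive field", {
  cfg <- encoder_config(conv_channels = c(3L, 4L), conv_kernel = 5L,
                        pool1_stride = 1L, pooled_length = 48L,
                        kernel_upper = 3L, kernel_lower = 5L,
                        tdfe_channels = 4L, feat_dim = 8L)
  params <- init_encoder_params(cfg, n_v = 2L, seed = 6)
  x <- array(rnorm(2 * 48), c(2L, 48L, 1L))
  base <- causalecg:::conv1d_forward(x, params[["enc.conv1.W"]],
                                     params[["enc.conv1.b"]], 5L)$y
  ## perturb sample 40; receptive field at t = 10 (radius 2) cannot move
  x2 <- x
  x2[, 40, 1] <- x2[, 40, 1] + 100
  pert <- causalecg:::conv1d_forward(x2, params[["enc.conv1.W"]],
                                     params[["enc.conv1.b"]], 5L)$y
  expect_identical(base[, 1:30, 1], pert[, 1:30, 1])
  expect_false(identical(base[, 38:42, 1], pert[, 38:42, 1]))
})

test_that("encoding is a pure deterministic function of input and params", {
  cfg <- tiny_model_config()
  params <- init_encoder_params(cfg$encoder, n_v = 2L, seed = 8)
  v <- matrix(rnorm(2 * 200), 2, 200)
  a <- encode_view(v, cfg$encoder, params)
  b <- encode_view(v, cfg$encoder, params)
  expect_identical(a$values, b$values)
})
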
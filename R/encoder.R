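## Convolutional view encoding and the dual-kernel time-domain features
## embedding (TDFE). Each two-lead view passes through a shared stack of 1-D
## convolutions (stride 1, zero "same" padding) with ReLU, an intermediate
## average pooling, and adaptive average pooling to a fixed length; per-view
## feature maps are averaged into one map, which the TDFE maps through two
## parallel conv branches with a small and a large kernel (short-term
## fluctuations vs long-term trends), each globally pooled and linearly
## projected to a D-dimensional feature vector.

#' Encoder configuration
#'
#' @param conv_channels integer vector of channel widths after each conv
#'   layer (input has `n_v = 2` channels).
#' @param conv_kernel odd kernel size of the view conv layers.
#' @param pool1_stride stride of the average pooling between conv layers
#'   (1 = none).
#' @param pooled_length adaptive-average-pool target length after the last
#'   conv layer.
#' @param kernel_upper,kernel_lower TDFE kernel sizes (defaults 5 and 50:
#'   small kernels capture short-term fluctuations, large ones long-term
#'   trends). The ablation grid (40/20, 40/10, 50/20, 50/10) is reachable
#'   here.
#' @param tdfe_channels channel width of the TDFE conv branches.
#' @param feat_dim D, the dimension of `f_upper` / `f_lower`.
#' @return an `encoder_config`.
#' @export
encoder_config <- function(conv_channels = c(8L, 16L), conv_kernel = 7L,
                           pool1_stride = 4L, pooled_length = 125L,
                           kernel_upper = 5L, kernel_lower = 50L,
                           tdfe_channels = 16L, feat_dim = 64L) {
  if (any(c(conv_channels, conv_kernel, pooled_length, kernel_upper,
            kernel_lower, tdfe_channels, feat_dim) < 1L))
    stop("all encoder sizes must be >= 1", call. = FALSE)
  if (pooled_length < kernel_lower)
    stop(sprintf(paste("pooled_length (%d) must be >= kernel_lower (%d);",
                       "choose a smaller lower kernel"),
                 pooled_length, kernel_lower), call. = FALSE)
  structure(list(conv_channels = as.integer(conv_channels),
                 conv_kernel = as.integer(conv_kernel),
                 pool1_stride = as.integer(pool1_stride),
                 pooled_length = as.integer(pooled_length),
                 kernel_upper = as.integer(kernel_upper),
                 kernel_lower = as.integer(kernel_lower),
                 tdfe_channels = as.integer(tdfe_channels),
                 feat_dim = as.integer(feat_dim)),
            class = "encoder_config")
}

#' Initialize encoder + TDFE parameters
#' @param config an [encoder_config()].
#' @param n_v leads per view (2 for the pair schemes).
#' @param seed integer seed.
#' @return flat named list of parameter arrays.
#' @export
init_encoder_params <- function(config, n_v = 2L, seed = 1L) {
  k <- config$conv_kernel
  ch <- c(n_v, config$conv_channels)
  tc <- config$tdfe_channels
  cl <- config$conv_channels[length(config$conv_channels)]
  with_seed(seed, {
    p <- list()
    for (i in seq_along(config$conv_channels)) {
      p[[sprintf("enc.conv%d.W", i)]] <-
        he_init(ch[i + 1L], ch[i] * k, ch[i] * k)
      p[[sprintf("enc.conv%d.b", i)]] <- numeric(ch[i + 1L])
    }
    p[["tdfe.up.W"]] <- he_init(tc, cl * config$kernel_upper,
                                cl * config$kernel_upper)
    p[["tdfe.up.b"]] <- numeric(tc)
    p[["tdfe.lo.W"]] <- he_init(tc, cl * config$kernel_lower,
                                cl * config$kernel_lower)
    p[["tdfe.lo.b"]] <- numeric(tc)
    p[["tdfe.up.lin.W"]] <- he_init(config$feat_dim, tc, tc)
    p[["tdfe.up.lin.b"]] <- numeric(config$feat_dim)
    p[["tdfe.lo.lin.W"]] <- he_init(config$feat_dim, tc, tc)
    p[["tdfe.lo.lin.b"]] <- numeric(config$feat_dim)
    ## single-path fallback used when the TDFE is ablated
    p[["notdfe.lin.W"]] <- he_init(config$feat_dim, cl, cl)
    p[["notdfe.lin.b"]] <- numeric(config$feat_dim)
    p
  })
}

## ---- batched internals -----------------------------------------------------

## TRUE when the fused compiled two-layer encoder kernel applies
enc_fast_path <- function(x, config) {
  length(config$conv_channels) == 2L &&
    dim(x)[2L] %% config$pool1_stride == 0L &&
    dim(x)[2L] >= config$conv_kernel &&
    dim(x)[2L] %/% config$pool1_stride >= config$conv_kernel
}

## x: (n_v, L, N) stacked views; returns (C_last, pooled_length, N) plus cache
encoder_forward <- function(x, params, config, want_cache = TRUE) {
  if (dim(x)[2L] < config$conv_kernel)
    stop(sprintf("input length %d is shorter than kernel %d; need L >= %d",
                 dim(x)[2L], config$conv_kernel, config$conv_kernel),
         call. = FALSE)
  if (enc_fast_path(x, config)) {
    y <- .enc_fwd_cpp(x, params[["enc.conv1.W"]], params[["enc.conv1.b"]],
                      params[["enc.conv2.W"]], params[["enc.conv2.b"]],
                      config$conv_kernel, config$conv_kernel,
                      config$pool1_stride, config$pooled_length)
    return(list(y = y, cache = if (want_cache) list(fused = TRUE, x = x)))
  }
  encoder_generic_forward(x, params, config, want_cache = want_cache)
}

## reference layer-by-layer path; also covers non-default encoder shapes
encoder_generic_forward <- function(x, params, config, want_cache = TRUE) {
  k <- config$conv_kernel
  caches <- list()
  h <- x
  for (i in seq_along(config$conv_channels)) {
    cv <- conv1d_forward(h, params[[sprintf("enc.conv%d.W", i)]],
                         params[[sprintf("enc.conv%d.b", i)]], k)
    rl <- relu_forward(cv$y)
    h <- rl$y
    caches[[sprintf("conv%d", i)]] <- if (want_cache) cv$cache else NULL
    caches[[sprintf("relu%d", i)]] <- if (want_cache) rl$cache else NULL
    if (i == 1L && config$pool1_stride > 1L) {
      L1 <- dim(h)[2L]
      pf <- pool_forward(h, L1 %/% config$pool1_stride)
      h <- pf$y
      caches[["pool1"]] <- pf$cache
    }
  }
  pf <- pool_forward(h, config$pooled_length)
  caches[["adapt"]] <- pf$cache
  list(y = pf$y, cache = caches)
}

encoder_backward <- function(dy, params, config, cache) {
  if (isTRUE(cache$fused)) {
    g <- .enc_bwd_cpp(dy, cache$x,
                      params[["enc.conv1.W"]], params[["enc.conv1.b"]],
                      params[["enc.conv2.W"]], params[["enc.conv2.b"]],
                      config$conv_kernel, config$conv_kernel,
                      config$pool1_stride, config$pooled_length)
    return(list(dx = NULL,
                grads = list(enc.conv1.W = g$dW1,
                             enc.conv1.b = as.numeric(g$db1),
                             enc.conv2.W = g$dW2,
                             enc.conv2.b = as.numeric(g$db2))))
  }
  grads <- list()
  dh <- pool_backward(dy, cache[["adapt"]])
  for (i in rev(seq_along(config$conv_channels))) {
    if (i == 1L && !is.null(cache[["pool1"]]))
      dh <- pool_backward(dh, cache[["pool1"]])
    dh <- relu_backward(dh, cache[[sprintf("relu%d", i)]])
    bk <- conv1d_backward(dh, params[[sprintf("enc.conv%d.W", i)]],
                          cache[[sprintf("conv%d", i)]])
    grads[[sprintf("enc.conv%d.W", i)]] <- bk$dW
    grads[[sprintf("enc.conv%d.b", i)]] <- bk$db
    dh <- bk$dx
  }
  list(dx = dh, grads = grads)
}

## mean across the M views of each record; x: (C, P, M*B) grouped per record
aggregate_forward <- function(x, M) {
  d <- dim(x); C <- d[1L]; P <- d[2L]; B <- d[3L] %/% M
  xm <- matrix(x, C * P)                        # columns = views
  dim(xm) <- c(C * P, M, B)
  y <- colMeans(aperm(xm, c(2L, 1L, 3L)))       # mean over M
  dim(y) <- c(C, P, B)
  list(y = y, M = M, dims = d)
}

aggregate_backward <- function(dy, M, dims) {
  d <- dim(dy); C <- d[1L]; P <- d[2L]; B <- d[3L]
  dym <- matrix(dy / M, C * P)
  dx <- array(0, c(C * P, M, B))
  for (m in seq_len(M)) dx[, m, ] <- dym
  dim(dx) <- dims
  dx
}

## one TDFE branch: conv(k) + ReLU + GAP + linear -> (D, B)
tdfe_branch_forward <- function(fm, W, b, Wl, bl, k) {
  cv <- conv1d_forward(fm, W, b, k)
  rl <- relu_forward(cv$y)
  gp <- gap_forward(rl$y)
  ln <- linear_forward(gp$y, Wl, bl)
  list(y = ln$y, cache = list(conv = cv$cache, relu = rl$cache,
                              gap = gp$cache, lin = ln$cache))
}

tdfe_branch_backward <- function(dy, W, Wl, cache) {
  lb <- linear_backward(dy, Wl, cache$lin)
  dg <- gap_backward(lb$dx, cache$gap)
  dr <- relu_backward(dg, cache$relu)
  cb <- conv1d_backward(dr, W, cache$conv)
  list(dfm = cb$dx, dW = cb$dW, db = cb$db, dWl = lb$dW, dbl = lb$db)
}

## ---- spec-level operations -------------------------------------------------

#' Encode one view through the shared convolutional stack
#'
#' 1-D convolutions (stride 1, zero "same" padding) with ReLU, intermediate
#' average pooling, then adaptive average pooling to `pooled_length`.
#'
#' @param view numeric `n_v x L` matrix (one view of a recording).
#' @param config an [encoder_config()].
#' @param params parameters from [init_encoder_params()].
#' @return a `feature_map`: list with `values` (`channels x pooled_length`)
#'   and `view_index`.
#' @export
encode_view <- function(view, config, params) {
  if (!is.matrix(view)) stop("`view` must be a matrix", call. = FALSE)
  x <- array(view, c(nrow(view), ncol(view), 1L))
  out <- encoder_forward(x, params, config, want_cache = FALSE)
  structure(list(values = matrix(out$y, dim(out$y)[1L], dim(out$y)[2L]),
                 view_index = NA_integer_),
            class = "feature_map")
}

#' Element-wise mean of per-view feature maps
#' @param maps list of `feature_map`s of identical shape.
#' @return a `feature_map` (the mean).
#' @export
aggregate_views <- function(maps) {
  if (length(maps) == 0L) stop("no feature maps supplied", call. = FALSE)
  vals <- lapply(maps, function(m) {
    if (inherits(m, "feature_map")) m$values else m
  })
  d0 <- dim(vals[[1L]])
  ok <- vapply(vals, function(v) identical(dim(v), d0), logical(1))
  if (!all(ok))
    stop("feature maps differ in shape", call. = FALSE)
  structure(list(values = Reduce(`+`, vals) / length(vals),
                 view_index = NA_integer_),
            class = "feature_map")
}

#' Dual-kernel time-domain features embedding
#'
#' Applies two parallel 1-D convolution branches with kernel sizes
#' `kernel_upper` and `kernel_lower` to an aggregated feature map, each
#' followed by ReLU, global average pooling, and a linear map to dimension D.
#'
#' @param fm a `feature_map` (or `channels x pooled_length` matrix).
#' @param config an [encoder_config()].
#' @param params parameters from [init_encoder_params()].
#' @return a `tdfe_output`: list with `f_upper` and `f_lower` (length-D
#'   vectors).
#' @export
tdfe <- function(fm, config, params) {
  v <- if (inherits(fm, "feature_map")) fm$values else fm
  if (ncol(v) < config$kernel_lower)
    stop(sprintf(paste("pooled length %d is shorter than kernel_lower %d;",
                       "choose a smaller lower kernel"),
                 ncol(v), config$kernel_lower), call. = FALSE)
  x <- array(v, c(nrow(v), ncol(v), 1L))
  up <- tdfe_branch_forward(x, params[["tdfe.up.W"]], params[["tdfe.up.b"]],
                            params[["tdfe.up.lin.W"]],
                            params[["tdfe.up.lin.b"]], config$kernel_upper)
  lo <- tdfe_branch_forward(x, params[["tdfe.lo.W"]], params[["tdfe.lo.b"]],
                            params[["tdfe.lo.lin.W"]],
                            params[["tdfe.lo.lin.b"]], config$kernel_lower)
  structure(list(f_upper = as.numeric(up$y), f_lower = as.numeric(lo$y)),
            class = "tdfe_output")
}
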
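## Full network assembly: shared view encoder -> view aggregation -> TDFE ->
## two causal branches (upper/lower), each with its own confounder dictionary,
## key/value projections, transformer block, MLP and linear head. Ablation
## flags: use_tdfe = FALSE collapses the dual-kernel embedding to a single
## linear feature path (one branch); use_cr = FALSE bypasses the
## dictionary/attention/transformer module in every branch.

#' Full model configuration
#'
#' @param n_leads number of input leads.
#' @param scheme view scheme name or [view_scheme()].
#' @param K_classes number of output classes.
#' @param encoder an [encoder_config()].
#' @param n_heads transformer attention heads.
#' @param ff_dim transformer feed-forward width.
#' @param link `"softmax"` (single-label) or `"sigmoid"` (multi-label scores).
#' @param use_tdfe,use_cr ablation switches for the time-domain features
#'   embedding and the causal-reasoning module.
#' @return a `model_config`.
#' @export
model_config <- function(n_leads = 12L, scheme = "pairs_12", K_classes = 4L,
                         encoder = encoder_config(), n_heads = 4L,
                         ff_dim = 128L, link = c("softmax", "sigmoid"),
                         use_tdfe = TRUE, use_cr = TRUE) {
  link <- match.arg(link)
  if (!inherits(scheme, "view_scheme")) scheme <- view_scheme(scheme)
  if (scheme$n_leads != n_leads)
    stop("view scheme covers ", scheme$n_leads, " leads but n_leads = ",
         n_leads, call. = FALSE)
  structure(list(n_leads = as.integer(n_leads), scheme = scheme,
                 K_classes = as.integer(K_classes), encoder = encoder,
                 n_heads = as.integer(n_heads), ff_dim = as.integer(ff_dim),
                 link = link, use_tdfe = isTRUE(use_tdfe),
                 use_cr = isTRUE(use_cr)),
            class = "model_config")
}

#' Initialize all model parameters
#' @param config a [model_config()].
#' @param seed integer seed.
#' @return a `model_state`: list with `params` (flat named list), `config`,
#'   `dicts` (per-branch confounder dictionaries, initially `NULL`),
#'   `epoch = 0`.
#' @export
init_model <- function(config, seed = 1L) {
  n_v <- length(config$scheme$partition[[1L]])
  D <- config$encoder$feat_dim
  params <- init_encoder_params(config$encoder, n_v = n_v,
                                seed = derive_seed(seed, 1L))
  if (!config$use_tdfe) {
    ## drop the unused dual-kernel parameters from the graph
    keep <- !grepl("^tdfe\\.", names(params))
    params <- params[keep]
  } else {
    params <- params[names(params) != "notdfe.lin.W" &
                     names(params) != "notdfe.lin.b"]
  }
  branches <- if (config$use_tdfe) c("br1", "br2") else "br1"
  for (i in seq_along(branches))
    params <- c(params,
                init_branch_params(D, config$K_classes, ff_dim = config$ff_dim,
                                   use_cr = config$use_cr,
                                   prefix = branches[i],
                                   seed = derive_seed(seed, 10L + i)))
  structure(list(params = params, config = config, dicts = NULL,
                 epoch = 0L, best_val = NA_real_),
            class = "model_state")
}

#' Count trainable parameters
#' @param state a `model_state` (or a flat parameter list).
#' @return integer: total number of scalar parameters.
#' @export
count_parameters <- function(state) {
  params <- if (inherits(state, "model_state")) state$params else state
  sum(vapply(params, length, integer(1)))
}

#' Stack records into the view tensor consumed by the network
#'
#' Normalizes each record per lead, splits it into views, and stacks all
#' views into one `(n_v, L, M * n)` array (views of record i occupy slots
#' `(i-1)*M + 1 .. i*M`).
#'
#' @param records list of [ecg_record()].
#' @param config a [model_config()].
#' @return list with `x` (the array), `y` (K x n label matrix), `M`, `n`.
#' @export
prepare_tensors <- function(records, config) {
  n <- length(records)
  M <- length(config$scheme$partition)
  n_v <- length(config$scheme$partition[[1L]])
  L <- ncol(records[[1L]]$signals)
  x <- array(0, c(n_v, L, M * n))
  y <- matrix(0, config$K_classes, n)
  for (i in seq_len(n)) {
    vs <- split_views(normalize_record(records[[i]]), config$scheme)
    for (m in seq_len(M)) x[, , (i - 1L) * M + m] <- vs$views[[m]]
    if (!is.null(records[[i]]$labels)) y[, i] <- records[[i]]$labels
  }
  list(x = x, y = y, M = M, n = n)
}

## ---- full forward / backward ----------------------------------------------

## x: (n_v, L, M*B). Returns per-branch logits and caches.
model_forward <- function(params, config, x, M, dicts,
                          want_cache = TRUE, features_only = FALSE) {
  enc <- encoder_forward(x, params, config$encoder, want_cache = want_cache)
  agg <- aggregate_forward(enc$y, M)
  fm <- agg$y                               # (C, P, B)
  feats <- list()
  caches <- list(enc = enc$cache, agg = agg)
  if (config$use_tdfe) {
    up <- tdfe_branch_forward(fm, params[["tdfe.up.W"]], params[["tdfe.up.b"]],
                              params[["tdfe.up.lin.W"]],
                              params[["tdfe.up.lin.b"]],
                              config$encoder$kernel_upper)
    lo <- tdfe_branch_forward(fm, params[["tdfe.lo.W"]], params[["tdfe.lo.b"]],
                              params[["tdfe.lo.lin.W"]],
                              params[["tdfe.lo.lin.b"]],
                              config$encoder$kernel_lower)
    feats <- list(br1 = up$y, br2 = lo$y)
    caches$up <- up$cache; caches$lo <- lo$cache
  } else {
    gp <- gap_forward(fm)
    ln <- linear_forward(gp$y, params[["notdfe.lin.W"]],
                         params[["notdfe.lin.b"]])
    feats <- list(br1 = ln$y)
    caches$gap <- gp$cache; caches$lin <- ln$cache
  }
  if (features_only)
    return(list(features = feats, caches = NULL))
  logits <- list(); bcaches <- list()
  for (br in names(feats)) {
    bf <- branch_forward(feats[[br]], dicts[[br]], params, br,
                         n_heads = config$n_heads, use_cr = config$use_cr)
    logits[[br]] <- bf$logits
    bcaches[[br]] <- bf$cache
  }
  list(logits = logits, features = feats, caches = caches, bcaches = bcaches)
}

## dlogits: named list per branch (K x B); returns flat gradient list
model_backward <- function(params, config, fwd, dlogits) {
  grads <- list()
  dfm <- NULL
  for (br in names(dlogits)) {
    bb <- branch_backward(dlogits[[br]], params, br, fwd$bcaches[[br]])
    grads <- c(grads, bb$grads)
    if (config$use_tdfe) {
      cc <- if (br == "br1") fwd$caches$up else fwd$caches$lo
      Wc <- if (br == "br1") params[["tdfe.up.W"]] else params[["tdfe.lo.W"]]
      Wl <- if (br == "br1") params[["tdfe.up.lin.W"]]
            else params[["tdfe.lo.lin.W"]]
      tb <- tdfe_branch_backward(bb$df, Wc, Wl, cc)
      pre <- if (br == "br1") "tdfe.up" else "tdfe.lo"
      grads[[paste0(pre, ".W")]] <- tb$dW
      grads[[paste0(pre, ".b")]] <- tb$db
      grads[[paste0(pre, ".lin.W")]] <- tb$dWl
      grads[[paste0(pre, ".lin.b")]] <- tb$dbl
      dfm <- if (is.null(dfm)) tb$dfm else dfm + tb$dfm
    } else {
      lb <- linear_backward(bb$df, params[["notdfe.lin.W"]], fwd$caches$lin)
      grads[["notdfe.lin.W"]] <- lb$dW
      grads[["notdfe.lin.b"]] <- lb$db
      dfm <- gap_backward(lb$dx, fwd$caches$gap)
    }
  }
  dx_agg <- aggregate_backward(dfm, fwd$caches$agg$M, fwd$caches$agg$dims)
  eb <- encoder_backward(dx_agg, params, config$encoder, fwd$caches$enc)
  grads <- c(grads, eb$grads)
  grads
}

#' Refresh the per-branch confounder dictionaries
#'
#' Recomputes both dictionaries from the current encoder's features over the
#' supplied records (typically the full training split), in chunks.
#'
#' @param state a `model_state`.
#' @param x view tensor from [prepare_tensors()].
#' @param y K x n label matrix.
#' @param M views per record.
#' @param chunk forward-pass chunk size (records).
#' @return the state with updated `dicts`.
#' @export
refresh_dictionaries <- function(state, x, y, M, chunk = 128L) {
  feats <- extract_features(state$params, state$config, x, M, chunk = chunk)
  state$dicts <- lapply(feats, function(f) {
    suppressWarnings(build_dictionary(t(f), t(y)))
  })
  state
}

## forward features (no causal head) in chunks; returns list of (D, n)
extract_features <- function(params, config, x, M, chunk = 128L) {
  n <- dim(x)[3L] %/% M
  out <- NULL
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    sl <- x[, , ((s - 1L) * M + 1L):(e * M), drop = FALSE]
    fw <- model_forward(params, config, sl, M, dicts = NULL,
                        want_cache = FALSE, features_only = TRUE)
    if (is.null(out)) out <- lapply(fw$features, function(f) matrix(0, nrow(f), n))
    for (br in names(fw$features)) out[[br]][, s:e] <- fw$features[[br]]
  }
  out
}

#' Predict class scores for a set of records
#'
#' Runs the full network and averages the per-branch score vectors
#' (the two branches are symmetric at inference time).
#'
#' @param state a trained `model_state`.
#' @param records list of [ecg_record()] (or a prepared tensor list).
#' @param chunk forward-pass chunk size.
#' @return n x K score matrix.
#' @export
predict_model <- function(state, records, chunk = 128L) {
  stopifnot(inherits(state, "model_state"))
  config <- state$config
  if (config$use_cr && is.null(state$dicts))
    stop("model has no confounder dictionaries; train it or call ",
         "refresh_dictionaries()", call. = FALSE)
  tens <- if (is.list(records) && !is.null(records$x)) records
          else prepare_tensors(records, config)
  n <- tens$n; M <- tens$M
  scores <- matrix(0, n, config$K_classes)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    sl <- tens$x[, , ((s - 1L) * M + 1L):(e * M), drop = FALSE]
    fw <- model_forward(state$params, config, sl, M, state$dicts,
                        want_cache = FALSE)
    acc <- 0
    for (br in names(fw$logits)) {
      sc <- if (config$link == "softmax") softmax_cols(fw$logits[[br]])
            else sigmoid(fw$logits[[br]])
      acc <- acc + t(sc)
    }
    scores[s:e, ] <- acc / length(fw$logits)
  }
  scores
}

#' Save / load a model state
#'
#' The checkpoint is a single file holding all parameter arrays by name, the
#' configuration, dictionaries, epoch counter and RNG-relevant seeds; reloads
#' restore bit-identical forward passes.
#'
#' @param state a `model_state`.
#' @param path checkpoint path (.rds).
#' @return `path` / the restored `model_state`.
#' @export
save_model_state <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model_state
#' @export
load_model_state <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "model_state"))
    stop("'", path, "' does not contain a model_state", call. = FALSE)
  state
}
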
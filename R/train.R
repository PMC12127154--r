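## Training: two-branch cross-entropy (L_total = a1 L_ce1 + a2 L_ce2), Adam
## with cosine-annealed learning rate, mini-batches, per-epoch confounder-
## dictionary refresh, best-state selection by validation macro-AUC.

#' Training configuration
#'
#' @param alpha1,alpha2 branch loss weights (non-negative, not both zero).
#' @param lr initial Adam learning rate.
#' @param schedule `"cosine"` (annealed to 0 over the epochs) or `"constant"`.
#' @param batch_size mini-batch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience on validation macro-AUC.
#' @param clip_norm global gradient-norm clip.
#' @param seed integer seed for shuffling and initialization.
#' @param dict_refresh `"per_epoch"` (recompute dictionaries from the current
#'   encoder at the start of every epoch) or `"frozen"` (warm-start once).
#' @return a `train_config`.
#' @export
train_config <- function(alpha1 = 0.5, alpha2 = 0.5, lr = 1e-3,
                         schedule = c("cosine", "constant"), batch_size = 64L,
                         epochs = 30L, patience = 5L, clip_norm = 5,
                         seed = 1L, dict_refresh = c("per_epoch", "frozen")) {
  schedule <- match.arg(schedule)
  dict_refresh <- match.arg(dict_refresh)
  stop_if_not_scalar_num(alpha1, "alpha1", lo = 0)
  stop_if_not_scalar_num(alpha2, "alpha2", lo = 0)
  if (alpha1 + alpha2 <= 0)
    stop("alpha1 and alpha2 must not both be zero", call. = FALSE)
  stop_if_not_scalar_num(lr, "lr", lo = .Machine$double.xmin)
  stop_if_not_scalar_num(batch_size, "batch_size", lo = 1)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, lr = lr,
                 schedule = schedule, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 clip_norm = clip_norm, seed = as.integer(seed),
                 dict_refresh = dict_refresh),
            class = "train_config")
}

#' Cross-entropy loss of one branch
#'
#' Softmax link: mean over samples of `-sum_k y_k log z_k` on probability
#' scores. Sigmoid link: mean over samples of the summed per-label binary
#' cross-entropy. Scores are clamped at 1e-12 before the log.
#'
#' @param scores n x K score matrix (probabilities).
#' @param targets n x K 0/1 matrix.
#' @param link `"softmax"` or `"sigmoid"`.
#' @return non-negative scalar.
#' @export
branch_loss <- function(scores, targets, link = c("softmax", "sigmoid")) {
  link <- match.arg(link)
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (is.null(dim(targets))) targets <- matrix(targets, nrow = 1L)
  if (!all(dim(scores) == dim(targets)))
    stop("scores and targets must have identical shape", call. = FALSE)
  z <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  if (link == "softmax") mean(rowSums(-targets * log(z)))
  else mean(rowSums(-targets * log(z) - (1 - targets) * log(1 - z)))
}

#' Combine branch losses
#'
#' `L_total = alpha1 * L_ce1 + alpha2 * L_ce2`.
#'
#' @param L1,L2 non-negative branch losses (`L2 = 0` for single-branch
#'   configurations).
#' @param config a [train_config()] (or list with `alpha1`, `alpha2`).
#' @return a `loss_report`: list with `L_ce1`, `L_ce2`, `L_total`.
#' @export
total_loss <- function(L1, L2, config) {
  if (L1 < 0 || L2 < 0) stop("branch losses must be >= 0", call. = FALSE)
  structure(list(L_ce1 = L1, L_ce2 = L2,
                 L_total = config$alpha1 * L1 + config$alpha2 * L2),
            class = "loss_report")
}

#' Cosine-annealed learning rate
#'
#' `lr(e) = lr0 * (1 + cos(pi (e - 1) / (E - 1))) / 2`: equals `lr0` at epoch
#' 1, decays monotonically, reaches 0 at the final epoch.
#'
#' @param epoch 1-based epoch index.
#' @param config a [train_config()].
#' @return learning rate for `epoch`.
#' @export
cosine_lr <- function(epoch, config) {
  if (config$schedule == "constant" || config$epochs <= 1L) return(config$lr)
  config$lr * (1 + cos(pi * (epoch - 1) / (config$epochs - 1))) / 2
}

## loss + dlogits for one branch; logits (K, B), y (K, B)
loss_and_grad <- function(logits, y, link) {
  B <- ncol(logits)
  if (link == "softmax") {
    p <- softmax_cols(logits)
    L <- branch_loss(t(p), t(y), link = "softmax")
    dz <- (sweep(p, 2L, colSums(y), "*") - y) / B
  } else {
    p <- sigmoid(logits)
    L <- branch_loss(t(p), t(y), link = "sigmoid")
    dz <- (p - y) / B
  }
  list(loss = L, dlogits = dz, scores = p)
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip_norm)
    grads <- lapply(grads, function(g) g * (clip_norm / gn))
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt, grad_norm = gn)
}

## ---- training loop ---------------------------------------------------------

#' Train the causal ECG classifier
#'
#' Mini-batch Adam with cosine annealing, per-epoch confounder-dictionary
#' refresh (the dictionaries are recomputed from the current encoder over the
#' full training split at the start of every epoch; before the first epoch
#' they are warm-started from the untrained encoder), validation after every
#' epoch, and best-state selection by validation macro-AUC with early
#' stopping. Fully seeded: identical inputs reproduce identical runs.
#'
#' @param datasets list with `train` and `val`, each a list of
#'   [ecg_record()] objects (labels attached).
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param verbose print one line per epoch to stderr.
#' @return list with `state` (best `model_state`) and `history` (data frame:
#'   epoch, lr, train losses, val loss, val macro-AUC).
#' @export
train_model <- function(datasets, config, tconfig = train_config(),
                        verbose = FALSE) {
  if (length(datasets$train) == 0L || length(datasets$val) == 0L)
    stop("`datasets` must contain non-empty `train` and `val`", call. = FALSE)
  tr <- prepare_tensors(datasets$train, config)
  va <- prepare_tensors(datasets$val, config)
  state <- init_model(config, seed = tconfig$seed)
  opt <- adam_init(state$params)
  if (config$use_cr)
    state <- refresh_dictionaries(state, tr$x, tr$y, tr$M)
  M <- tr$M
  n <- tr$n
  link <- config$link
  a <- c(br1 = tconfig$alpha1, br2 = tconfig$alpha2)
  if (!config$use_tdfe) a <- c(br1 = tconfig$alpha1 + tconfig$alpha2)
  history <- NULL
  best <- list(auc = -Inf, state = NULL, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(tconfig$epochs)) {
    lr <- cosine_lr(epoch, tconfig)
    if (config$use_cr && tconfig$dict_refresh == "per_epoch" && epoch > 1L)
      state <- refresh_dictionaries(state, tr$x, tr$y, tr$M)
    perm <- with_seed(derive_seed(tconfig$seed, 1000L + epoch),
                      sample.int(n))
    ep_loss <- c(br1 = 0, br2 = 0); ep_total <- 0; nb <- 0L
    for (s in seq(1L, n, by = tconfig$batch_size)) {
      ix <- perm[s:min(s + tconfig$batch_size - 1L, n)]
      vix <- as.vector(t(outer(ix - 1L, seq_len(M), function(i, m) i * M + m)))
      xb <- tr$x[, , vix, drop = FALSE]
      yb <- tr$y[, ix, drop = FALSE]
      fw <- model_forward(state$params, config, xb, M, state$dicts)
      dlog <- list(); Ls <- c(br1 = 0, br2 = 0)
      for (br in names(fw$logits)) {
        lg <- loss_and_grad(fw$logits[[br]], yb, link)
        Ls[br] <- lg$loss
        dlog[[br]] <- a[[br]] * lg$dlogits
      }
      a2 <- if ("br2" %in% names(a)) a[["br2"]] else 0
      lt <- total_loss(Ls[["br1"]], Ls[["br2"]],
                       list(alpha1 = a[["br1"]], alpha2 = a2))
      if (!is.finite(lt$L_total))
        stop(sprintf("divergent (non-finite) loss at epoch %d, batch %d",
                     epoch, nb + 1L), call. = FALSE)
      grads <- model_backward(state$params, config, fw, dlog)
      st <- adam_step(state$params, grads, opt, lr,
                      clip_norm = tconfig$clip_norm)
      state$params <- st$params; opt <- st$opt
      ep_loss <- ep_loss + Ls; ep_total <- ep_total + lt$L_total
      nb <- nb + 1L
    }
    state$epoch <- epoch
    fwv <- model_forward(state$params, config, va$x, va$M, state$dicts,
                         want_cache = FALSE)
    vls <- vapply(fwv$logits, function(lg)
      loss_and_grad(lg, va$y, link)$loss, numeric(1))
    vl <- mean(vls)
    val_scores <- Reduce(`+`, lapply(fwv$logits, function(lg) {
      if (link == "softmax") t(softmax_cols(lg)) else t(sigmoid(lg))
    })) / length(fwv$logits)
    vm <- tryCatch(compute_metrics(val_scores, t(va$y)),
                   error = function(e) list(macro_auc = NA_real_))
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr,
      train_L1 = ep_loss[["br1"]] / nb, train_L2 = ep_loss[["br2"]] / nb,
      train_total = ep_total / nb, val_loss = vl,
      val_macro_auc = vm$macro_auc))
    if (verbose)
      message(sprintf(
        "epoch %2d  lr %.2e  train %.4f  val %.4f  val_auc %.4f",
        epoch, lr, ep_total / nb, vl, vm$macro_auc))
    if (!is.na(vm$macro_auc) && vm$macro_auc > best$auc + 1e-12) {
      best <- list(auc = vm$macro_auc, state = state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tconfig$patience) break
    }
  }
  out_state <- best$state %||% state
  out_state$best_val <- best$auc
  list(state = out_state, history = history)
}

#' Finite-difference gradient check on a random parameter subset
#'
#' Compares backpropagated gradients of the total loss against central
#' finite differences for `n_params` randomly chosen scalar parameters.
#'
#' @param config a [model_config()] (keep it tiny).
#' @param L signal length of the probe batch.
#' @param B probe batch size.
#' @param n_params number of scalar parameters to probe.
#' @param eps finite-difference step.
#' @param seed integer seed.
#' @return data frame with analytic and numeric gradients and relative error.
#' @export
gradient_check <- function(config, L = 64L, B = 3L, n_params = 10L,
                           eps = 1e-5, seed = 42L) {
  M <- length(config$scheme$partition)
  n_v <- length(config$scheme$partition[[1L]])
  state <- init_model(config, seed = seed)
  probe <- with_seed(derive_seed(seed, 7L), {
    x <- array(rnorm(n_v * L * M * B, sd = 0.5), c(n_v, L, M * B))
    y <- matrix(0, config$K_classes, B)
    y[cbind(sample.int(config$K_classes, B, replace = TRUE), seq_len(B))] <- 1
    feats <- matrix(rnorm(config$encoder$feat_dim * 20L),
                    20L, config$encoder$feat_dim)
    labs <- matrix(0, 20L, config$K_classes)
    labs[cbind(seq_len(20L),
               sample.int(config$K_classes, 20L, replace = TRUE))] <- 1
    list(x = x, y = y, feats = feats, labs = labs)
  })
  if (config$use_cr) {
    d <- build_dictionary(probe$feats, probe$labs)
    state$dicts <- list(br1 = d, br2 = d)
  }
  a <- if (config$use_tdfe) c(br1 = 0.5, br2 = 0.5) else c(br1 = 1)
  loss_fn <- function(params) {
    fw <- model_forward(params, config, probe$x, M, state$dicts,
                        want_cache = FALSE)
    sum(vapply(names(fw$logits), function(br)
      a[[br]] * loss_and_grad(fw$logits[[br]], probe$y, config$link)$loss,
      numeric(1)))
  }
  fw <- model_forward(state$params, config, probe$x, M, state$dicts)
  dlog <- list()
  for (br in names(fw$logits))
    dlog[[br]] <- a[[br]] *
      loss_and_grad(fw$logits[[br]], probe$y, config$link)$dlogits
  grads <- model_backward(state$params, config, fw, dlog)
  picks <- with_seed(derive_seed(seed, 8L), {
    nms <- sample(names(grads), n_params, replace = TRUE)
    lapply(nms, function(nm) list(nm = nm,
                                  i = sample.int(length(grads[[nm]]), 1L)))
  })
  res <- lapply(picks, function(pk) {
    p_plus <- state$params; p_minus <- state$params
    p_plus[[pk$nm]][pk$i] <- p_plus[[pk$nm]][pk$i] + eps
    p_minus[[pk$nm]][pk$i] <- p_minus[[pk$nm]][pk$i] - eps
    num <- (loss_fn(p_plus) - loss_fn(p_minus)) / (2 * eps)
    ana <- grads[[pk$nm]][pk$i]
    data.frame(param = pk$nm, index = pk$i, analytic = ana, numeric = num,
               ## the 1e-6 floor keeps exactly-zero gradients (e.g. the key
               ## bias, which softmax cancels) from amplifying FD noise
               rel_err = abs(ana - num) / max(abs(ana), abs(num), 1e-6))
  })
  do.call(rbind, res)
}
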
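## Mini-batch training with Adam; ablation variants; convergence study.

tree_zeros <- function(g) {
  if (is.list(g)) lapply(g, tree_zeros) else g * 0
}

## One Adam step over the gradient tree; returns updated params and moments.
adam_step <- function(params, grads, m, v, lr, beta1, beta2, eps, t) {
  walk <- function(p, g, m1, v1) {
    if (is.list(g)) {
      for (nm in names(g)) {
        res <- walk(p[[nm]], g[[nm]], m1[[nm]], v1[[nm]])
        p[[nm]] <- res$p; m1[[nm]] <- res$m; v1[[nm]] <- res$v
      }
      return(list(p = p, m = m1, v = v1))
    }
    m1 <- beta1 * m1 + (1 - beta1) * g
    v1 <- beta2 * v1 + (1 - beta2) * g * g
    mh <- m1 / (1 - beta1^t)
    vh <- v1 / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m1, v = v1)
  }
  res <- walk(params, grads, m, v)
  names(res) <- c("params", "m", "v")
  res
}

#' Training configuration
#'
#' Adam hyperparameters default to the customary `lr = 1e-3`,
#' `beta1 = 0.9`, `beta2 = 0.999`; batch size defaults to 32. A random
#' 90/10 train/validation split (controlled by `seed`) feeds the per-epoch
#' validation metrics only — all parameter updates use the training split.
#'
#' @param epochs Number of passes over the training split.
#' @param batch_size Mini-batch size.
#' @param lr,beta1,beta2,adam_eps Adam hyperparameters.
#' @param lambda Auxiliary-loss weight (ignored by the plain variant).
#' @param seed Integer seed controlling initialisation, the split and the
#'   epoch-level shuffles; a run is bit-reproducible given the seed.
#' @param variant Model variant, see [model_config()].
#' @param val_fraction Fraction held out for validation metrics (0 disables).
#' @param patience Optional early-stopping patience: stop when the training
#'   classification loss has not improved for this many epochs.
#' @param verbose Print a loss line per epoch?
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 32L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         lambda = 1, seed = 1L, variant = "smtl",
                         val_fraction = 0.1, patience = NULL,
                         verbose = FALSE) {
  stopifnot(is_count(epochs), is_count(batch_size), lr > 0, lambda >= 0,
            val_fraction >= 0, val_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 lambda = lambda, seed = as.integer(seed),
                 variant = normalize_variant(variant),
                 val_fraction = val_fraction, patience = patience,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Assemble an (initialised) model variant
#'
#' * `smtl`: bidirectional encoder; the auxiliary count is the serial sum of
#'   the predicted label probabilities.
#' * `parallel`: ordinary hard-parameter-sharing multi-task model — same
#'   trunk, but the count comes from an independent linear regression head,
#'   so it is not tied to the label probabilities.
#' * `plain`: classification only; the auxiliary loss is dropped.
#' * `unidirectional`: the serial model with a single forward GRU (the
#'   representation and dense stack shrink to `hidden_dim`).
#'
#' @param variant Variant tag (`parallel_mtl` is accepted for `parallel`).
#' @param space A `label_space`.
#' @param embeddings An [embedding_table()].
#' @param model_cfg Optional [model_config()] template; its variant and
#'   label/embedding dimensions are overridden to match the arguments.
#' @param seed Initialisation seed.
#' @param lambda Auxiliary-loss weight recorded in the configuration.
#' @return A `model_params` object.
#' @export
build_variant <- function(variant, space, embeddings, model_cfg = NULL,
                          seed = 1L, lambda = 1) {
  variant <- normalize_variant(variant)
  if (is.null(model_cfg)) {
    model_cfg <- model_config(n_labels = length(space$labels),
                              embedding_dim = embeddings$dim,
                              variant = variant, lambda = lambda)
  } else {
    model_cfg <- model_config(n_labels = length(space$labels),
                              embedding_dim = embeddings$dim,
                              max_len = model_cfg$max_len,
                              hidden_dim = model_cfg$hidden_dim,
                              variant = variant, lambda = lambda,
                              activation = model_cfg$activation,
                              bn_momentum = model_cfg$bn_momentum,
                              bn_eps = model_cfg$bn_eps,
                              trainable_embeddings = model_cfg$trainable_embeddings)
  }
  params <- init_params(model_cfg, embeddings, seed = seed)
  params$labels <- space$labels
  params
}

apply_bn_updates <- function(params, upd) {
  params$bn1$mean <- upd$bn1$mean; params$bn1$var <- upd$bn1$var
  params$bn2$mean <- upd$bn2$mean; params$bn2$var <- upd$bn2$var
  params
}

#' Train a model
#'
#' Mini-batch Adam on the joint loss over shuffled epochs. Batch norm uses
#' batch statistics during updates and accumulates running statistics for
#' inference. A non-finite loss aborts with a diagnostic naming the epoch and
#' batch. Fully reproducible given `config$seed`.
#'
#' @param corpus A list of citations, or an `encoded_corpus` carrying `y`/`z`
#'   (then `space`/`max_len` are taken from it).
#' @param space A `label_space`.
#' @param embeddings An [embedding_table()].
#' @param config A [train_config()].
#' @param model_cfg Optional [model_config()]; defaults to the reference
#'   dimensions, which are sized for MEDLINE-scale corpora — pass a smaller
#'   configuration for desk-scale work.
#' @param policy Decision policy used for the per-epoch validation metrics.
#' @return List of class `smtl_fit` with `params` (trained `model_params`)
#'   and `history` (one row per completed epoch: losses and validation
#'   micro-precision/recall/F and count MSE).
#' @export
train_model <- function(corpus, space, embeddings, config = train_config(),
                        model_cfg = NULL, policy = decision_policy()) {
  stopifnot(inherits(config, "train_config"))
  params <- build_variant(config$variant, space, embeddings,
                          model_cfg = model_cfg, seed = config$seed,
                          lambda = config$lambda)
  cfg <- params$config
  enc <- if (inherits(corpus, "encoded_corpus")) corpus else
    encode_corpus(corpus, embeddings, max_len = cfg$max_len, space = space)
  if (is.null(enc$y)) fail("encoded corpus lacks gold labels; pass `space` to encode_corpus()")
  n <- nrow(enc$idx)
  if (n == 0L) fail("empty corpus")
  set.seed(config$seed)
  n_val <- floor(config$val_fraction * n)
  val_ids <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  train_ids <- setdiff(seq_len(n), val_ids)
  eff_lambda <- if (cfg$variant == "plain") 0 else config$lambda
  m <- NULL; v <- NULL; t_step <- 0L
  hist <- vector("list", config$epochs)
  best <- Inf; stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_ids)
    nb <- ceiling(length(perm) / config$batch_size)
    ep_loss <- ep_pri <- ep_aux <- 0
    for (b in seq_len(nb)) {
      ids <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, length(perm))]
      fwd <- model_forward(params, enc$idx[ids, , drop = FALSE],
                           enc$mask[ids, , drop = FALSE],
                           mode = "train", keep_cache = TRUE)
      yb <- enc$y[ids, , drop = FALSE]; zb <- enc$z[ids]
      lo <- total_loss(yb, fwd$P, zb, fwd$R, lambda = eff_lambda)
      if (!is.finite(lo$loss)) {
        fail("non-finite loss at epoch %d, batch %d (L_pri=%g, L_aux=%g)",
             epoch, b, lo$loss_pri, lo$loss_aux)
      }
      grads <- model_backward(params, fwd, yb, zb)
      params <- apply_bn_updates(params, fwd$bn_updates)
      if (is.null(m)) { m <- tree_zeros(grads); v <- tree_zeros(grads) }
      t_step <- t_step + 1L
      upd <- adam_step(params[names(grads)], grads, m, v, config$lr,
                       config$beta1, config$beta2, config$adam_eps, t_step)
      params[names(grads)] <- upd$params
      m <- upd$m; v <- upd$v
      w <- length(ids) / length(perm)
      ep_pri <- ep_pri + w * lo$loss_pri
      ep_aux <- ep_aux + w * lo$loss_aux
    }
    ep_loss <- ep_pri + ep_aux
    rec <- data.frame(epoch = epoch, loss = ep_loss, loss_pri = ep_pri,
                      loss_aux = ep_aux, val_precision = NA_real_,
                      val_recall = NA_real_, val_f = NA_real_,
                      val_mse = NA_real_)
    if (length(val_ids) > 0) {
      pv <- model_forward(params, enc$idx[val_ids, , drop = FALSE],
                          enc$mask[val_ids, , drop = FALSE], mode = "inference")
      pred_sets <- decide_labels(pv, policy)
      gold_sets <- apply(enc$y[val_ids, , drop = FALSE], 1L, function(r) which(r > 0),
                         simplify = FALSE)
      mm <- micro_prf(pred_sets, gold_sets)
      rec$val_precision <- mm[["precision"]]
      rec$val_recall <- mm[["recall"]]
      rec$val_f <- mm[["f_measure"]]
      rec$val_mse <- regression_mse(pv$R, enc$z[val_ids])
    }
    hist[[epoch]] <- rec
    if (config$verbose) {
      message(sprintf("epoch %3d  L=%.4f  L_pri=%.4f  L_aux=%.4f  val_F=%s",
                      epoch, ep_loss, ep_pri, ep_aux,
                      ifelse(is.na(rec$val_f), "-", sprintf("%.3f", rec$val_f))))
    }
    if (!is.null(config$patience)) {
      if (ep_pri < best - 1e-6) { best <- ep_pri; stall <- 0L } else stall <- stall + 1L
      if (stall >= config$patience) { hist <- hist[seq_len(epoch)]; break }
    }
  }
  history <- do.call(rbind, hist)
  class(history) <- c("training_history", "data.frame")
  structure(list(params = params, history = history, config = config),
            class = "smtl_fit")
}

#' @export
print.smtl_fit <- function(x, ...) {
  h <- x$history
  cat("<smtl_fit> variant=", x$params$config$variant, ", ",
      nrow(h), " epochs; final L_pri=", sprintf("%.4f", h$loss_pri[nrow(h)]),
      if (!is.na(h$val_f[nrow(h)])) sprintf(", val micro-F=%.3f", h$val_f[nrow(h)]) else "",
      "\n", sep = "")
  invisible(x)
}

#' Cross-entropy of the label-prior predictor
#'
#' The primary loss incurred by always predicting each label's empirical
#' frequency: the sum over labels of the binary entropies of the column
#' means. Used as a variant-independent convergence threshold — falling below
#' it means the model has learnt more than the label base rates.
#'
#' @param y `N x M` 0/1 label matrix.
#' @param eps Clipping constant for degenerate frequencies.
#' @return Scalar.
#' @export
prior_baseline_bce <- function(y, eps = 1e-7) {
  p <- pmin(pmax(colMeans(y), eps), 1 - eps)
  -sum(p * log(p) + (1 - p) * log(1 - p))
}

#' Epochs needed to reach a classification-loss threshold
#'
#' @param history A `training_history`.
#' @param threshold Target `loss_pri`.
#' @return First epoch with `loss_pri <= threshold`, or (number of epochs
#'   + 1) when never reached (right-censored).
#' @export
epochs_to_threshold <- function(history, threshold) {
  hit <- which(history$loss_pri <= threshold)
  if (length(hit) == 0L) nrow(history) + 1L else hit[1L]
}

#' Convergence study across model variants
#'
#' Trains each variant from several seeds on the same corpus and records how
#' many epochs each run needs to push the classification loss below a common
#' threshold (default: the label-prior cross-entropy of the corpus,
#' [prior_baseline_bce()]), along with the final classification loss.
#'
#' @inheritParams train_model
#' @param variants Character vector of variant tags.
#' @param seeds Integer vector of run seeds.
#' @param threshold Loss threshold; `NULL` for the prior baseline.
#' @return Data frame with one row per (variant, seed): `epochs_to_threshold`
#'   (censored at epochs + 1) and `final_loss_pri`; the threshold is attached
#'   as attribute `"threshold"`.
#' @export
convergence_study <- function(corpus, space, embeddings,
                              config = train_config(),
                              model_cfg = NULL,
                              variants = c("smtl", "parallel", "plain", "unidirectional"),
                              seeds = 1:5, threshold = NULL) {
  enc <- if (inherits(corpus, "encoded_corpus")) corpus else {
    mc <- if (is.null(model_cfg)) model_config(length(space$labels),
                                               embedding_dim = embeddings$dim)
          else model_cfg
    encode_corpus(corpus, embeddings, max_len = mc$max_len, space = space)
  }
  if (is.null(threshold)) threshold <- prior_baseline_bce(enc$y)
  rows <- list()
  for (variant in variants) {
    for (seed in seeds) {
      cfg <- config
      cfg$variant <- normalize_variant(variant)
      cfg$seed <- as.integer(seed)
      fit <- train_model(enc, space, embeddings, config = cfg,
                         model_cfg = model_cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = cfg$variant, seed = seed,
        epochs_to_threshold = epochs_to_threshold(fit$history, threshold),
        final_loss_pri = fit$history$loss_pri[nrow(fit$history)])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}
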
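## Desk-scale benchmark experiments. These fix the two study designs the
## package's evaluation rests on: the variant convergence comparison and the
## label-recovery run. Both are sized for minutes on one CPU; the methods
## vignette discusses the choices.

#' The reference synthetic corpus
#'
#' [synthetic_config()] defaults (2,000 citations, 50 labels, Zipf 1.1, mean
#' cardinality 13, 10% word noise) with the given seed.
#'
#' @param seed Generator seed.
#' @return As [generate_corpus()].
#' @export
reference_corpus <- function(seed = 1L) {
  generate_corpus(synthetic_config(seed = as.integer(seed)))
}

#' Desk-scale model configuration
#'
#' The reference architecture shrunk to corpus scale: 50-dimensional
#' embeddings (matching the generator), a 64-token window and 32 hidden
#' units per direction. Depth, batch-norm placement, the serial count head
#' and all structural choices are those of the full model; only widths and
#' the sequence window shrink.
#'
#' @param variant Model variant.
#' @param ... Overrides passed to [model_config()].
#' @return A [model_config()].
#' @export
desk_model_config <- function(variant = "smtl", ...) {
  args <- modifyList(list(n_labels = 50L, embedding_dim = 50L, max_len = 64L,
                          hidden_dim = 32L, variant = variant), list(...))
  do.call(model_config, args)
}

#' Variant convergence benchmark
#'
#' Trains all four variants from `length(seeds)` seeds each on the reference
#' corpus and measures epochs to push the training classification loss below
#' the corpus's label-prior cross-entropy, plus the final classification
#' loss. Runs not reaching the threshold are censored at `epochs + 1`.
#'
#' @param corpus_seed Seed for the reference corpus.
#' @param seeds Training seeds (one run per variant per seed).
#' @param epochs Epoch budget per run.
#' @return As [convergence_study()], plus a `"medians"` attribute: per-variant
#'   median epochs-to-threshold and median final loss.
#' @export
run_convergence_benchmark <- function(corpus_seed = 1L, seeds = 1:5,
                                      epochs = 15L) {
  sim <- reference_corpus(corpus_seed)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 64L,
                       space = sim$space)
  res <- convergence_study(enc, sim$space, sim$embeddings,
                           config = train_config(epochs = epochs,
                                                 val_fraction = 0),
                           model_cfg = desk_model_config(),
                           seeds = seeds)
  med <- do.call(rbind, lapply(split(res, res$variant), function(d) {
    data.frame(variant = d$variant[1],
               median_epochs = stats::median(d$epochs_to_threshold),
               median_final_loss_pri = stats::median(d$final_loss_pri))
  }))
  rownames(med) <- NULL
  attr(res, "medians") <- med
  res
}

#' Label-recovery benchmark
#'
#' Trains the serial model on a noise-free reference-sized corpus and
#' measures how well it recovers the generating label sets: micro-P/R/F
#' under the count-driven decision policy and the count MSE, both on the
#' full corpus. Because the generator's random embeddings carry no semantic
#' structure (unlike pre-trained word2vec vectors), the embedding table is
#' fine-tuned; the model is widened to 64 hidden units and a 128-token
#' window so the whole document is visible.
#'
#' @param seed Seed for both the corpus and the training run.
#' @param epochs Training epochs.
#' @return List with `metrics` (precision/recall/f_measure/mse),
#'   `count_variance` (variance of the true label counts — the mean
#'   predictor's MSE), `history`, and `n` (corpus size).
#' @export
run_recovery_benchmark <- function(seed = 1L, epochs = 40L) {
  sim <- generate_corpus(synthetic_config(noise_rate = 0,
                                          seed = as.integer(seed)))
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 128L,
                       space = sim$space)
  mc <- model_config(n_labels = 50L, embedding_dim = 50L, max_len = 128L,
                     hidden_dim = 64L, variant = "smtl",
                     trainable_embeddings = TRUE)
  fit <- train_model(enc, sim$space, sim$embeddings,
                     config = train_config(epochs = epochs, lr = 2e-3,
                                           seed = as.integer(seed),
                                           val_fraction = 0),
                     model_cfg = mc)
  metrics <- evaluate_predictions(predict_corpus(fit$params, enc), enc)
  list(metrics = metrics, count_variance = stats::var(enc$z),
       history = fit$history, n = length(sim$corpus))
}
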
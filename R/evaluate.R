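## Label decisions and BioASQ-style evaluation metrics.

#' Label decision policy
#'
#' Two ways to binarise per-label probabilities:
#' * `top_k_from_count` (default): keep the `k` highest-probability labels
#'   with `k = clip(round(R), 0, M)`, `R` being the predicted soft label
#'   count — the count-driven dynamic threshold that motivates the auxiliary
#'   regression task. Rounding is half-away-from-zero; ties in probability
#'   keep the lower label index.
#' * `fixed_threshold`: keep every label with probability at or above a fixed
#'   cut (default 0.5).
#'
#' @param mode `"top_k_from_count"` or `"fixed_threshold"`.
#' @param threshold Cut point for the fixed mode, in (0, 1).
#' @return List of class `decision_policy`.
#' @export
decision_policy <- function(mode = c("top_k_from_count", "fixed_threshold"),
                            threshold = 0.5) {
  mode <- match.arg(mode)
  if (!(threshold > 0 && threshold < 1)) fail("threshold must lie in (0, 1)")
  structure(list(mode = mode, threshold = threshold), class = "decision_policy")
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

decide_one <- function(P, R, policy) {
  M <- length(P)
  if (policy$mode == "fixed_threshold") {
    which(P >= policy$threshold)
  } else {
    k <- min(max(round_half_away(R), 0), M)
    if (k <= 0) integer(0) else sort(order(-P, seq_len(M))[seq_len(k)])
  }
}

#' Turn predicted probabilities into label index sets
#'
#' @param pred Either a list with elements `P` (vector or `n x M` matrix) and
#'   `R` (scalar or length-n vector) — e.g. the output of [model_forward()] —
#'   or a bare probability vector (then `R` defaults to its sum).
#' @param policy A [decision_policy()].
#' @return Integer vector of label indices (1-based), or a list of such
#'   vectors for matrix input. Under the count policy the set size is exactly
#'   `clip(round(R), 0, M)`.
#' @export
decide_labels <- function(pred, policy = decision_policy()) {
  if (is.numeric(pred)) pred <- list(P = pred, R = sum(pred))
  P <- pred$P; R <- pred$R
  if (is.matrix(P)) {
    lapply(seq_len(nrow(P)), function(i) decide_one(P[i, ], R[i], policy))
  } else {
    decide_one(P, R, policy)
  }
}

#' Micro-averaged precision, recall and F-measure
#'
#' True/false positives and false negatives are pooled over all
#' citation-label pairs before computing the ratios — the headline metrics of
#' the BioASQ semantic-indexing challenge. Conventions: precision is 0 when
#' nothing is predicted, recall is 0 when there is no gold label, and F is 0
#' when P + R = 0.
#'
#' @param predicted,gold Aligned lists of label sets (integer or character
#'   vectors; each treated as a set).
#' @return Named numeric vector `precision`, `recall`, `f_measure`.
#' @export
micro_prf <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    fail("micro_prf: %d predictions vs %d gold sets", length(predicted), length(gold))
  }
  tp <- fp <- fn <- 0L
  for (i in seq_along(predicted)) {
    p <- unique(predicted[[i]]); g <- unique(gold[[i]])
    ntp <- length(intersect(p, g))
    tp <- tp + ntp
    fp <- fp + length(p) - ntp
    fn <- fn + length(g) - ntp
  }
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f_measure = f)
}

#' Mean square error of the count regression
#'
#' `mean((z - R)^2)`; the auxiliary-task metric (no lambda factor).
#'
#' @param R Predicted counts, or a list with an `R` element.
#' @param z True label counts.
#' @return Scalar.
#' @export
regression_mse <- function(R, z) {
  if (is.list(R)) R <- R$R
  if (length(R) != length(z)) fail("regression_mse: length(R) != length(z)")
  mean((z - R)^2)
}

#' Predict labels for a corpus
#'
#' Inference-mode forward pass in chunks, then label decisions.
#'
#' @param params Trained `model_params`.
#' @param enc An `encoded_corpus` (encode with the model's `max_len`).
#' @param policy A [decision_policy()].
#' @param chunk Mini-batch size used for the forward passes (memory knob
#'   only; results are independent of it).
#' @return List with `P`, `R`, and `sets` (list of label index vectors).
#' @export
predict_corpus <- function(params, enc, policy = decision_policy(),
                           chunk = 256L) {
  n <- nrow(enc$idx)
  M <- params$config$n_labels
  P <- matrix(NA_real_, n, M)
  R <- numeric(n)
  start <- 1L
  while (start <= n) {
    ids <- start:min(start + chunk - 1L, n)
    fw <- model_forward(params, enc$idx[ids, , drop = FALSE],
                        enc$mask[ids, , drop = FALSE], mode = "inference")
    P[ids, ] <- fw$P
    R[ids] <- fw$R
    start <- start + chunk
  }
  list(P = P, R = R, sets = decide_labels(list(P = P, R = R), policy))
}

#' Evaluate predictions against gold labels
#'
#' @param pred Output of [predict_corpus()] (or any list with `sets` and `R`).
#' @param enc An `encoded_corpus` carrying `y` and `z`.
#' @return Named numeric vector: micro `precision`, `recall`, `f_measure`,
#'   and count `mse`.
#' @export
evaluate_predictions <- function(pred, enc) {
  gold <- apply(enc$y, 1L, function(r) which(r > 0), simplify = FALSE)
  m <- micro_prf(pred$sets, gold)
  c(m, mse = regression_mse(pred$R, enc$z))
}
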
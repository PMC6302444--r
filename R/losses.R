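## Joint training objective: per-label cross-entropy plus the weighted
## mean-square label-count loss.

#' Primary multi-label cross-entropy loss
#'
#' Bernoulli cross-entropy summed over labels and averaged over the
#' mini-batch:
#' `L_pri = -(1/N) sum_i sum_j [ y_ij log P_ij + (1 - y_ij) log(1 - P_ij) ]`.
#' Note the *sum* over labels (not a mean), so the value scales with M — a
#' chance-level prediction of 1/2 everywhere costs `M * log 2`.
#' Probabilities are clipped to `[eps, 1 - eps]` before the logarithms; the
#' clip is a no-op on interior values.
#'
#' @param y `N x M` 0/1 ground-truth matrix (or a vector for N = 1).
#' @param P Predicted probabilities, same shape as `y`.
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss.
#' @export
primary_loss <- function(y, P, eps = 1e-7) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1L)
  if (!is.matrix(P)) P <- matrix(P, nrow = 1L)
  if (!all(dim(y) == dim(P))) {
    fail("primary_loss: y is %dx%d but P is %dx%d", nrow(y), ncol(y), nrow(P), ncol(P))
  }
  if (!all(y %in% c(0, 1))) fail("primary_loss: y entries must be 0 or 1")
  Pc <- pmin(pmax(P, eps), 1 - eps)
  -sum(y * log(Pc) + (1 - y) * log(1 - Pc)) / nrow(y)
}

#' Auxiliary label-count regression loss
#'
#' Weighted mean-square error between the true label counts and the
#' predicted soft counts: `L_aux = (lambda / N) sum_i (z_i - R_i)^2`.
#'
#' @param z True label counts (length N).
#' @param R Predicted counts (length N).
#' @param lambda Non-negative weight of the auxiliary task (default 1).
#' @return Scalar loss.
#' @export
auxiliary_loss <- function(z, R, lambda = 1) {
  if (length(z) != length(R)) fail("auxiliary_loss: length(z) != length(R)")
  if (lambda < 0) fail("auxiliary_loss: lambda must be non-negative")
  lambda * mean((z - R)^2)
}

#' Joint loss
#'
#' `L = L_pri + L_aux`, exactly additive.
#'
#' @inheritParams primary_loss
#' @inheritParams auxiliary_loss
#' @return List with `loss`, `loss_pri`, `loss_aux`.
#' @export
total_loss <- function(y, P, z, R, lambda = 1, eps = 1e-7) {
  lp <- primary_loss(y, P, eps = eps)
  la <- auxiliary_loss(z, R, lambda = lambda)
  list(loss = lp + la, loss_pri = lp, loss_aux = la)
}
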
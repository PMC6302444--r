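## Backward pass: analytic gradients of the joint loss with respect to every
## trainable parameter. Layout of the returned gradient tree mirrors the
## trainable entries of `model_params`.

bn_backward <- function(dy, bnc, gamma) {
  n <- nrow(dy)
  dgamma <- colSums(dy * bnc$xhat)
  dbeta <- colSums(dy)
  gi <- gamma * bnc$istd
  ## dx = gamma*istd * (dy - mean(dy) - xhat * mean(dy*xhat)), means over batch
  dx <- sweep(dy, 2L, dbeta / n) - sweep(bnc$xhat, 2L, dgamma / n, `*`)
  dx <- sweep(dx, 2L, gi, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

act_backward <- function(dD, pre_act_out, post_act, kind) {
  if (kind == "relu") dD * (pre_act_out > 0) else dD * (1 - post_act^2)
}

## Gradient of the loss at the output layer, folded with the sigmoid:
## d L_pri / d logits = (P - y) / N. The serial count layer adds
## d L_aux / d P_ij = (2 lambda / N)(R_i - z_i) for every j (the all-ones dot
## product spreads the count residual uniformly over labels), carried through
## the sigmoid as an extra (..) * P(1-P) term on the logits.
model_backward <- function(params, fwd, y, z) {
  cfg <- params$config
  cache <- fwd$cache
  P <- fwd$P; R <- fwd$R
  n <- nrow(P)
  lambda <- cfg$lambda
  dlogits <- (P - y) / n
  dR <- NULL
  if (cfg$variant %in% c("smtl", "unidirectional") && lambda > 0) {
    dlogits <- dlogits + (2 * lambda / n) * (R - z) * (P * (1 - P))
  }
  grads <- list()
  D2 <- cache$D2
  grads$out <- list(W = t(dlogits) %*% D2, b = colSums(dlogits))
  dD2 <- dlogits %*% params$out$W
  if (cfg$variant == "parallel" && lambda > 0) {
    dR <- (2 * lambda / n) * (R - z)
    grads$reg <- list(W = matrix(dR, 1L) %*% D2, b = sum(dR))
    dD2 <- dD2 + outer(dR, drop(params$reg$W))
  } else if (cfg$variant == "parallel") {
    grads$reg <- list(W = matrix(0, 1L, cfg$rep_dim), b = 0)
  }
  dB2 <- act_backward(dD2, cache$b2$y, D2, cfg$activation)
  bb2 <- bn_backward(dB2, cache$b2, params$bn2$gamma)
  grads$bn2 <- list(gamma = bb2$dgamma, beta = bb2$dbeta)
  dA2 <- bb2$dx
  grads$dense2 <- list(W = t(dA2) %*% cache$D1, b = colSums(dA2))
  dD1 <- dA2 %*% params$dense2$W
  dB1 <- act_backward(dD1, cache$b1$y, cache$D1, cfg$activation)
  bb1 <- bn_backward(dB1, cache$b1, params$bn1$gamma)
  grads$bn1 <- list(gamma = bb1$dgamma, beta = bb1$dbeta)
  dA1 <- bb1$dx
  grads$dense1 <- list(W = t(dA1) %*% cache$H, b = colSums(dA1))
  dH <- dA1 %*% params$dense1$W
  u <- cfg$hidden_dim
  want_dx <- isTRUE(cfg$trainable_embeddings)
  gback <- function(X, mask, g, gcache, dh) {
    gru_backward_cpp(X, mask, g$Wz, g$Uz, g$Wr, g$Ur, g$Wc, g$Uc,
                     gcache$Z, gcache$R, gcache$HC, gcache$HP, dh, want_dx)
  }
  if (cfg$variant == "unidirectional") {
    gf <- gback(cache$X, cache$mask, params$gru_f, cache$gf, dH)
    grads$gru_f <- list(Wz = gf$dWz, Uz = gf$dUz, Wr = gf$dWr, Ur = gf$dUr,
                        Wc = gf$dWc, Uc = gf$dUc)
    dX_list <- if (want_dx) list(list(dX = gf$dX, rev = FALSE)) else NULL
  } else {
    gf <- gback(cache$X, cache$mask, params$gru_f, cache$gf,
                dH[, seq_len(u), drop = FALSE])
    gb <- gback(cache$Xr, cache$maskr, params$gru_b, cache$gb,
                dH[, u + seq_len(u), drop = FALSE])
    grads$gru_f <- list(Wz = gf$dWz, Uz = gf$dUz, Wr = gf$dWr, Ur = gf$dUr,
                        Wc = gf$dWc, Uc = gf$dUc)
    grads$gru_b <- list(Wz = gb$dWz, Uz = gb$dUz, Wr = gb$dWr, Ur = gb$dUr,
                        Wc = gb$dWc, Uc = gb$dUc)
    dX_list <- if (want_dx) {
      list(list(dX = gf$dX, rev = FALSE), list(dX = gb$dX, rev = TRUE))
    } else NULL
  }
  if (want_dx) {
    d <- cfg$embedding_dim
    L <- ncol(cache$idx)
    nb <- nrow(cache$idx)
    demb <- matrix(0, nrow(params$emb), d)
    for (piece in dX_list) {
      ## flatten the n x d x L cube to (n*L) x d with (citation, step) rows
      flat <- aperm(piece$dX, c(1L, 3L, 2L))
      dim(flat) <- c(nb * L, d)
      idx_cols <- if (piece$rev) cache$idx[, L:1, drop = FALSE] else cache$idx
      agg <- rowsum(flat, group = as.vector(idx_cols) + 1L)
      rows <- as.integer(rownames(agg))
      demb[rows, ] <- demb[rows, , drop = FALSE] + agg
    }
    demb[1L, ] <- 0  # OOV/padding row stays fixed at zero
    grads$emb <- demb
  }
  grads
}
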
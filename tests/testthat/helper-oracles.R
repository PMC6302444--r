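# Independent oracles and shared fixtures. The oracles deliberately use
# straight-line scalar code (explicit loops, no matrix algebra) so they share
# no code path with the implementation they check.

# Scalar-loop GRU step: per-element evaluation of the gate equations.
oracle_gru_step <- function(x, h_prev, params) {
  u <- nrow(params$Wz)
  d <- ncol(params$Wz)
  h_new <- numeric(u)
  for (j in seq_len(u)) {
    az <- 0; ar <- 0
    for (k in seq_len(d)) {
      az <- az + params$Wz[j, k] * x[k]
      ar <- ar + params$Wr[j, k] * x[k]
    }
    for (k in seq_len(u)) {
      az <- az + params$Uz[j, k] * h_prev[k]
      ar <- ar + params$Ur[j, k] * h_prev[k]
    }
    z <- 1 / (1 + exp(-az))
    r_jk_sum <- 0
    for (k in seq_len(d)) r_jk_sum <- r_jk_sum + params$Wc[j, k] * x[k]
    # reset gate applies element-wise to h_prev before the recurrent product,
    # so the full reset vector is needed; compute it per element k
    for (k in seq_len(u)) {
      ark <- 0
      for (m in seq_len(d)) ark <- ark + params$Wr[k, m] * x[m]
      for (m in seq_len(u)) ark <- ark + params$Ur[k, m] * h_prev[m]
      rk <- 1 / (1 + exp(-ark))
      r_jk_sum <- r_jk_sum + params$Uc[j, k] * (rk * h_prev[k])
    }
    hc <- tanh(r_jk_sum)
    h_new[j] <- (1 - z) * h_prev[j] + z * hc
  }
  h_new
}

# Scalar-loop run over a masked sequence (forward order only).
oracle_run_forward <- function(x_seq, mask, params) {
  h <- numeric(nrow(params$Wz))
  for (t in seq_len(nrow(x_seq))) {
    if (mask[t]) h <- oracle_gru_step(x_seq[t, ], h, params)
  }
  h
}

# Independent micro-averaged P/R/F via dense indicator matrices.
oracle_micro_prf <- function(predicted, gold, M) {
  n <- length(predicted)
  pm <- matrix(0L, n, M)
  gm <- matrix(0L, n, M)
  for (i in seq_len(n)) {
    pm[i, predicted[[i]]] <- 1L
    gm[i, gold[[i]]] <- 1L
  }
  tp <- sum(pm == 1L & gm == 1L)
  fp <- sum(pm == 1L & gm == 0L)
  fn <- sum(pm == 0L & gm == 1L)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f_measure = f)
}

# Small synthetic world shared by several test files.
tiny_sim <- function(seed = 7, n = 80, noise = 0.1) {
  generate_corpus(synthetic_config(
    n_citations = n, vocab_size = 240, n_labels = 6,
    mean_labels_per_citation = 2.5, doc_length_mean = 25, doc_length_max = 40,
    embedding_dim = 10, noise_rate = noise, seed = seed))
}

tiny_model_cfg <- function(variant = "smtl", ...) {
  model_config(n_labels = 6, embedding_dim = 10, max_len = 20, hidden_dim = 5,
               variant = variant, ...)
}

random_gru <- function(d, u, seed) gru_params(d, u, seed = seed)
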
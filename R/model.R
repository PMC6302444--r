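## The serial multi-task network: configuration, parameter initialisation,
## batched forward pass, and the count layer.

VARIANTS <- c("smtl", "parallel", "plain", "unidirectional")

normalize_variant <- function(variant) {
  v <- tolower(variant)
  v[v == "parallel_mtl"] <- "parallel"
  if (!v %in% VARIANTS) {
    fail("unknown variant '%s' (known: %s)", variant, paste(VARIANTS, collapse = ", "))
  }
  v
}

#' Model configuration
#'
#' Defaults mirror the reference setup for MEDLINE-scale semantic indexing:
#' 200-dimensional word embeddings, sequences truncated/padded to 360 words,
#' a GRU hidden state of 270 per direction (540 after concatenation), and two
#' 540-dimensional fully-connected layers before the sigmoid output layer.
#'
#' @param n_labels Number of labels M (output dimension).
#' @param embedding_dim Word-embedding dimension (default 200).
#' @param max_len Fixed sequence length (default 360).
#' @param hidden_dim GRU hidden dimension per direction (default 270).
#' @param variant One of `"smtl"` (serial count layer), `"parallel"`
#'   (ordinary hard-parameter-sharing MTL with an independent regression
#'   head), `"plain"` (classification only) or `"unidirectional"` (serial
#'   model with a single-direction GRU).
#' @param lambda Auxiliary-loss weight (default 1; ignored by `"plain"`).
#' @param activation Hidden dense activation, `"relu"` or `"tanh"`.
#' @param bn_momentum,bn_eps Batch-normalisation running-average momentum and
#'   variance floor.
#' @param trainable_embeddings Update the embedding table during training?
#'   The pre-trained vectors are frozen by default.
#' @return List of class `model_config`. `rep_dim` is the encoder output
#'   dimension (`2 * hidden_dim`, or `hidden_dim` for the unidirectional
#'   variant); the two hidden dense layers share this dimension.
#' @export
model_config <- function(n_labels, embedding_dim = 200L, max_len = 360L,
                         hidden_dim = 270L, variant = "smtl", lambda = 1,
                         activation = c("relu", "tanh"),
                         bn_momentum = 0.99, bn_eps = 1e-3,
                         trainable_embeddings = FALSE) {
  stopifnot(is_count(n_labels), is_count(embedding_dim), is_count(max_len),
            is_count(hidden_dim), lambda >= 0)
  variant <- normalize_variant(variant)
  activation <- match.arg(activation)
  rep_dim <- if (variant == "unidirectional") hidden_dim else 2L * hidden_dim
  structure(list(n_labels = as.integer(n_labels),
                 embedding_dim = as.integer(embedding_dim),
                 max_len = as.integer(max_len),
                 hidden_dim = as.integer(hidden_dim),
                 rep_dim = as.integer(rep_dim),
                 variant = variant, lambda = lambda, activation = activation,
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 trainable_embeddings = trainable_embeddings),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> variant=", x$variant,
      " d=", x$embedding_dim, " L=", x$max_len,
      " hidden=", x$hidden_dim, " rep=", x$rep_dim,
      " M=", x$n_labels, " lambda=", x$lambda, "\n", sep = "")
  invisible(x)
}

dense_init <- function(out_dim, in_dim) {
  list(W = xavier_matrix(out_dim, in_dim), b = numeric(out_dim))
}

bn_init <- function(p) {
  list(gamma = rep(1, p), beta = numeric(p), mean = numeric(p), var = rep(1, p))
}

#' Initialise all trainable parameters
#'
#' Weight matrices (GRU input and recurrent weights, dense layers) use the
#' Xavier uniform initialiser, `U(-b, b)` with `b = sqrt(6/(fan_in +
#' fan_out))`; every bias vector is exactly zero. Deterministic given `seed`.
#'
#' @param config A [model_config()].
#' @param embeddings An [embedding_table()] whose dimension matches
#'   `config$embedding_dim`.
#' @param seed Integer seed.
#' @return List of class `model_params`: embedding matrix (with a leading
#'   all-zero row serving OOV tokens and padding), GRU parameter sets,
#'   dense/batch-norm/output (and, for the parallel variant, regression-head)
#'   parameters, plus the config.
#' @export
init_params <- function(config, embeddings, seed = 1L) {
  if (embeddings$dim != config$embedding_dim) {
    fail("embedding table dimension %d != config embedding_dim %d",
         embeddings$dim, config$embedding_dim)
  }
  d <- config$embedding_dim; u <- config$hidden_dim
  p <- config$rep_dim; M <- config$n_labels
  params <- with_seed(seed, {
    pr <- list(gru_f = gru_params(d, u))
    if (config$variant != "unidirectional") pr$gru_b <- gru_params(d, u)
    pr$dense1 <- dense_init(p, p)
    pr$bn1 <- bn_init(p)
    pr$dense2 <- dense_init(p, p)
    pr$bn2 <- bn_init(p)
    pr$out <- dense_init(M, p)
    if (config$variant == "parallel") pr$reg <- dense_init(1L, p)
    pr
  })
  params$emb <- rbind(numeric(d), embeddings$vectors)  # row 1 = OOV/padding
  params$tokens <- embeddings$tokens
  params$config <- config
  structure(params, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  print(x$config)
  cat("  vocabulary: ", length(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

relu <- function(x) (x > 0) * x

activate <- function(x, kind) if (kind == "relu") relu(x) else tanh(x)

## Batch norm, batch statistics (train) or running statistics (inference).
bn_forward <- function(A, bn, eps, mode) {
  if (mode == "train") {
    mu <- colMeans(A)
    v <- colMeans(A * A) - mu * mu
    v[v < 0] <- 0
  } else {
    mu <- bn$mean
    v <- bn$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(A, 2L, mu), 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, bn$gamma, `*`), 2L, bn$beta, `+`)
  list(y = y, xhat = xhat, istd = istd, mu = mu, v = v)
}

## Build the n x d x L input cube from the embedding matrix (leading zero row)
## and an n x L 0-based index matrix.
embed_cube <- function(emb, idx) {
  n <- nrow(idx); L <- ncol(idx); d <- ncol(emb)
  X <- array(0, c(n, d, L))
  for (t in seq_len(L)) X[, , t] <- emb[idx[, t] + 1L, , drop = FALSE]
  X
}

run_gru_batch <- function(X, mask, g, keep_cache) {
  gru_forward_cpp(X, mask, g$Wz, g$Uz, g$Wr, g$Ur, g$Wc, g$Uc, keep_cache)
}

#' Batched forward pass
#'
#' Embeds the index sequences, encodes them with the (bi)directional GRU,
#' applies the dense stack (affine, batch norm, activation, twice), the
#' sigmoid output layer, and the count layer. In `"train"` mode batch norm
#' uses batch statistics (and the returned `bn_updates` carry refreshed
#' running statistics); in `"inference"` mode it uses the stored running
#' statistics, making the pass a pure function of `(idx, mask, params)`.
#'
#' @param params A [init_params()] result.
#' @param idx `n x L` integer matrix of 0-based embedding-row indices (0 =
#'   OOV/padding row), as produced by [encode_corpus()].
#' @param mask `n x L` logical (or 0/1) matrix marking real tokens.
#' @param mode `"inference"` or `"train"`.
#' @param keep_cache Keep intermediate activations for the backward pass?
#' @return List with `P` (`n x M` per-label probabilities), `R` (length-n
#'   predicted label counts; equal to `rowSums(P)` for the serial variants,
#'   the regression head's output for `"parallel"`), `H` (encoder output),
#'   and optionally `cache` / `bn_updates`.
#' @export
model_forward <- function(params, idx, mask, mode = c("inference", "train"),
                          keep_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- params$config
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = 1L)
  if (!is.matrix(mask)) mask <- matrix(mask, nrow = 1L)
  storage.mode(idx) <- "integer"
  mmat <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  n <- nrow(idx); L <- ncol(idx)
  X <- embed_cube(params$emb, idx)
  gf <- run_gru_batch(X, mmat, params$gru_f, keep_cache)
  if (cfg$variant == "unidirectional") {
    H <- gf$h
    gb <- NULL; Xr <- NULL; mr <- NULL
  } else {
    Xr <- X[, , L:1, drop = FALSE]
    mr <- mmat[, L:1, drop = FALSE]
    gb <- run_gru_batch(Xr, mr, params$gru_b, keep_cache)
    H <- cbind(gf$h, gb$h)
  }
  A1 <- sweep(H %*% t(params$dense1$W), 2L, params$dense1$b, `+`)
  b1 <- bn_forward(A1, params$bn1, cfg$bn_eps, mode)
  D1 <- activate(b1$y, cfg$activation)
  A2 <- sweep(D1 %*% t(params$dense2$W), 2L, params$dense2$b, `+`)
  b2 <- bn_forward(A2, params$bn2, cfg$bn_eps, mode)
  D2 <- activate(b2$y, cfg$activation)
  logits <- sweep(D2 %*% t(params$out$W), 2L, params$out$b, `+`)
  P <- sigmoid(logits)
  R <- if (cfg$variant == "parallel") {
    drop(D2 %*% t(params$reg$W)) + params$reg$b
  } else {
    count_labels(P)
  }
  out <- list(P = P, R = R, H = H)
  if (mode == "train") {
    mom <- cfg$bn_momentum
    out$bn_updates <- list(
      bn1 = list(mean = mom * params$bn1$mean + (1 - mom) * b1$mu,
                 var = mom * params$bn1$var + (1 - mom) * b1$v),
      bn2 = list(mean = mom * params$bn2$mean + (1 - mom) * b2$mu,
                 var = mom * params$bn2$var + (1 - mom) * b2$v))
  }
  if (keep_cache) {
    out$cache <- list(X = X, Xr = Xr, mask = mmat, maskr = mr, idx = idx,
                      gf = gf, gb = gb, H = H, b1 = b1, D1 = D1, b2 = b2,
                      D2 = D2, logits = logits)
  }
  out
}

#' Count layer: soft predicted label count
#'
#' The dot product of the probability vector with the all-ones vector — i.e.
#' the sum of the per-label probabilities. Over the full 2017 MeSH vocabulary
#' the ones vector has 28,472 entries; here its length simply matches the
#' label space.
#'
#' @param P Probability vector, or `n x M` matrix (one row per citation);
#'   entries must lie in `[0, 1]`.
#' @return Scalar, or length-n vector for matrix input.
#' @export
count_labels <- function(P) {
  if (any(P < 0 | P > 1)) fail("count_labels: probabilities must lie in [0, 1]")
  if (is.matrix(P)) rowSums(P) else sum(P)
}
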
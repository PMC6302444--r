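## Model checkpoints: one JSON archive holding every parameter array, the
## model configuration and the label-space ordering. Full double precision
## (17 significant digits) so save/load round-trips bit-exactly for
## inference reproducibility.

## numeric payloads are written as %.17g strings: JSON numeric printing is
## not guaranteed to round-trip the last ulp, 17 significant digits are
ser_array <- function(x) {
  if (is.matrix(x)) list(dim = dim(x), data = sprintf("%.17g", as.vector(x)))
  else list(dim = length(x), data = sprintf("%.17g", as.vector(x)))
}

deser_array <- function(s) {
  d <- unlist(s$dim)
  x <- as.numeric(unlist(s$data))
  if (length(d) == 2L) matrix(x, d[1], d[2]) else x
}

ser_tree <- function(x) {
  if (is.numeric(x)) ser_array(x) else lapply(x, ser_tree)
}

deser_tree <- function(s) {
  if (!is.null(s$dim)) deser_array(s) else lapply(s, deser_tree)
}

PARAM_BLOCKS <- c("emb", "gru_f", "gru_b", "dense1", "bn1", "dense2", "bn2",
                  "out", "reg")

#' Save a trained model
#'
#' @param params A `model_params` object.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
save_model <- function(params, path) {
  blocks <- intersect(PARAM_BLOCKS, names(params))
  payload <- list(
    format = "smtl-checkpoint",
    version = as.character(utils::packageVersion("smtl")),
    config = unclass(params$config),
    labels = params$labels,
    tokens = params$tokens,
    params = lapply(params[blocks], ser_tree))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Path written by [save_model()].
#' @return A `model_params` object.
#' @export
load_model <- function(path) {
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE,
                          simplifyDataFrame = FALSE)
  if (!identical(s$format, "smtl-checkpoint")) {
    fail("%s is not a model checkpoint", path)
  }
  cfg <- s$config
  params <- lapply(s$params, deser_tree)
  params$config <- model_config(
    n_labels = cfg$n_labels, embedding_dim = cfg$embedding_dim,
    max_len = cfg$max_len, hidden_dim = cfg$hidden_dim,
    variant = cfg$variant, lambda = cfg$lambda, activation = cfg$activation,
    bn_momentum = cfg$bn_momentum, bn_eps = cfg$bn_eps,
    trainable_embeddings = isTRUE(cfg$trainable_embeddings))
  params$labels <- as.character(s$labels)
  params$tokens <- as.character(s$tokens)
  structure(params, class = "model_params")
}
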
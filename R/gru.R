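## Gated recurrent unit: cell, masked directional runs, bidirectional encoder.
##
## These single-sequence functions are the definitional implementation of the
## encoder; training uses batched compiled kernels that are tested for exact
## agreement with them.

#' Xavier (Glorot) uniform weight matrix
#'
#' Entries drawn uniformly on `±sqrt(6 / (fan_in + fan_out))` where for an
#' `out x in` matrix fan_in = `in` and fan_out = `out`.
#'
#' @param nrow,ncol Matrix dimensions (`out x in`).
#' @return Numeric matrix.
#' @export
xavier_matrix <- function(nrow, ncol) {
  bound <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -bound, bound), nrow, ncol)
}

#' GRU parameter set
#'
#' Six weight matrices: input weights `Wz`, `Wr`, `Wc` (`hidden_dim x
#' input_dim`) and recurrent weights `Uz`, `Ur`, `Uc` (`hidden_dim x
#' hidden_dim`) for the update gate, reset gate and candidate activation.
#' The cell has no bias terms. All matrices use Xavier uniform
#' initialisation (the recurrent matrices too — their initialisation is a
#' free choice, made identical to the input weights for uniformity).
#'
#' @param input_dim Input vector dimension.
#' @param hidden_dim Hidden state dimension (270 in the reference
#'   configuration).
#' @param seed Optional seed; when supplied the draw is deterministic and the
#'   caller's RNG stream is untouched.
#' @return List of class `gru_params`.
#' @export
gru_params <- function(input_dim, hidden_dim, seed = NULL) {
  draw <- function() {
    list(Wz = xavier_matrix(hidden_dim, input_dim),
         Uz = xavier_matrix(hidden_dim, hidden_dim),
         Wr = xavier_matrix(hidden_dim, input_dim),
         Ur = xavier_matrix(hidden_dim, hidden_dim),
         Wc = xavier_matrix(hidden_dim, input_dim),
         Uc = xavier_matrix(hidden_dim, hidden_dim))
  }
  p <- if (is.null(seed)) draw() else with_seed(seed, draw())
  p$input_dim <- input_dim
  p$hidden_dim <- hidden_dim
  structure(p, class = "gru_params")
}

check_gru_shapes <- function(x, h_prev, params) {
  d <- ncol(params$Wz); u <- nrow(params$Wz)
  if (length(x) != d) fail("gru_step: input has length %d, expected %d", length(x), d)
  if (length(h_prev) != u) fail("gru_step: state has length %d, expected %d", length(h_prev), u)
  for (nm in c("Uz", "Ur", "Uc")) {
    if (!all(dim(params[[nm]]) == c(u, u))) fail("gru_step: %s must be %d x %d", nm, u, u)
  }
  for (nm in c("Wr", "Wc")) {
    if (!all(dim(params[[nm]]) == c(u, d))) fail("gru_step: %s must be %d x %d", nm, u, d)
  }
  invisible(TRUE)
}

#' One GRU step
#'
#' Computes the update gate `z = sigmoid(Wz x + Uz h)`, reset gate
#' `r = sigmoid(Wr x + Ur h)`, candidate `hc = tanh(Wc x + Uc (r o h))`, and
#' the new state `h' = (1 - z) o h + z o hc` (element-wise; `o` is the
#' Hadamard product). With a zero state and zero input the state stays at
#' zero: the gates sit at 1/2 and the candidate at tanh(0) = 0.
#'
#' @param x Input vector (length `input_dim`).
#' @param h_prev Previous hidden state (length `hidden_dim`).
#' @param params A [gru_params()] list.
#' @return New hidden state vector.
#' @export
gru_step <- function(x, h_prev, params) {
  check_gru_shapes(x, h_prev, params)
  z <- sigmoid(drop(params$Wz %*% x + params$Uz %*% h_prev))
  r <- sigmoid(drop(params$Wr %*% x + params$Ur %*% h_prev))
  hc <- tanh(drop(params$Wc %*% x + params$Uc %*% (r * h_prev)))
  (1 - z) * h_prev + z * hc
}

#' Run a GRU over one masked sequence in one direction
#'
#' The initial state is the zero vector. Padded positions (mask FALSE) pass
#' the state through unchanged, so trailing padding never alters the result:
#' the forward final state is the state after the last valid token. The
#' backward direction processes the reversed sequence, so its final state is
#' the state after (originally) the first token.
#'
#' @param x_seq `L x input_dim` matrix of embedded tokens.
#' @param mask Logical vector of length `L`; must be trailing-padded (all
#'   valid positions precede all padded ones).
#' @param params A [gru_params()] list.
#' @param direction `"forward"` or `"backward"`.
#' @param return_states Also return the `L x hidden_dim` matrix of post-step
#'   states (in processing order)?
#' @return Final hidden state vector; with `return_states = TRUE`, a list
#'   with `h` and `states`.
#' @export
run_direction <- function(x_seq, mask, params,
                          direction = c("forward", "backward"),
                          return_states = FALSE) {
  direction <- match.arg(direction)
  x_seq <- as.matrix(x_seq)
  L <- nrow(x_seq)
  if (length(mask) != L) fail("mask length %d != sequence length %d", length(mask), L)
  mask <- as.logical(mask)
  if (is.unsorted(rev(mask))) fail("mask must be trailing-padded")
  if (!any(mask)) {
    warning("all-padded sequence; returning the zero state", call. = FALSE)
  }
  u <- nrow(params$Wz)
  h <- numeric(u)
  order <- if (direction == "forward") seq_len(L) else rev(seq_len(L))
  states <- if (return_states) matrix(0, L, u) else NULL
  k <- 0L
  for (t in order) {
    if (mask[t]) h <- gru_step(x_seq[t, ], h, params)
    k <- k + 1L
    if (return_states) states[k, ] <- h
  }
  if (return_states) list(h = h, states = states) else h
}

#' Bidirectional GRU encoding of one masked sequence
#'
#' Concatenates the forward-direction and backward-direction final states
#' into the hidden representation `H = [H_l; H_r]` of dimension
#' `2 * hidden_dim` (540 under the reference configuration of 270 per
#' direction).
#'
#' @inheritParams run_direction
#' @param fwd,bwd [gru_params()] for the two directions (equal `hidden_dim`).
#' @return Numeric vector of length `2 * hidden_dim`.
#' @export
bgru_encode <- function(x_seq, mask, fwd, bwd) {
  if (nrow(fwd$Wz) != nrow(bwd$Wz)) {
    fail("forward and backward GRUs must share hidden_dim")
  }
  c(run_direction(x_seq, mask, fwd, "forward"),
    run_direction(x_seq, mask, bwd, "backward"))
}
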
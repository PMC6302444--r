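## Word-embedding tables: construction and word2vec text/binary I/O.

#' Construct an embedding table
#'
#' @param tokens Character vector of vocabulary tokens (distinct).
#' @param vectors Numeric matrix, one row per token; all rows share the
#'   dimension `d` (200 in the reference configuration, where citations are
#'   represented by 200-dimensional word2vec vectors pre-trained on PubMed
#'   abstracts).
#' @return An `embedding_table`: list with `tokens`, `vectors`, `dim`.
#' @export
embedding_table <- function(tokens, vectors) {
  tokens <- as.character(tokens)
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "double"
  if (length(tokens) != nrow(vectors)) fail("one vector row per token required")
  if (anyDuplicated(tokens)) fail("embedding tokens must be distinct")
  if (!all(is.finite(vectors))) fail("embedding vectors must be finite")
  rownames(vectors) <- NULL
  structure(list(tokens = tokens, vectors = vectors, dim = ncol(vectors)),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", length(x$tokens), " tokens, d = ", x$dim, "\n",
      sep = "")
  invisible(x)
}

#' Look up one token's embedding vector
#'
#' Out-of-vocabulary tokens map to the all-zero vector: a zero input
#' contributes nothing to the GRU gate pre-activations while the position
#' stays mask-valid.
#'
#' @param table An [embedding_table()].
#' @param token Character scalar.
#' @return Numeric vector of length `table$dim`.
#' @export
lookup_embedding <- function(table, token) {
  i <- match(token, table$tokens)
  if (is.na(i)) numeric(table$dim) else table$vectors[i, ]
}

#' Read a word2vec embedding table
#'
#' Supports the two standard word2vec distribution formats: text (`"V d"`
#' header line, then `"token v1 ... vd"` lines) and binary (same ASCII
#' header, then per token the token bytes, a space, and `d` little-endian
#' float32 values, terminated by a newline). Duplicate tokens keep the first
#' occurrence with a warning; a header/body mismatch is an error.
#'
#' @param path Path to the embedding file.
#' @param format `"word2vec-text"` or `"word2vec-binary"`.
#' @return An [embedding_table()].
#' @export
load_embeddings <- function(path, format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("embedding file not found: %s", path)
  if (format == "word2vec-text") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 1L) fail("empty embedding file: %s", path)
    hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
    if (length(hdr) != 2L || anyNA(hdr)) fail("bad word2vec header in %s", path)
    V <- hdr[1]; d <- hdr[2]
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) != V) {
      fail("word2vec header declares %d tokens but body has %d lines", V, length(body))
    }
    parts <- strsplit(trimws(body), "[[:space:]]+")
    toks <- vapply(parts, `[[`, character(1), 1L)
    vecs <- matrix(NA_real_, V, d)
    for (i in seq_len(V)) {
      v <- suppressWarnings(as.numeric(parts[[i]][-1]))
      if (length(v) != d || anyNA(v)) {
        fail("token %s: expected %d values, got %d parseable", toks[i], d,
             sum(!is.na(v)))
      }
      vecs[i, ] <- v
    }
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr_chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) fail("bad word2vec binary header in %s", path)
      if (ch == "\n") break
      hdr_chars <- c(hdr_chars, ch)
    }
    hdr <- as.integer(strsplit(trimws(paste(hdr_chars, collapse = "")),
                               "[[:space:]]+")[[1]])
    if (length(hdr) != 2L || anyNA(hdr)) fail("bad word2vec binary header in %s", path)
    V <- hdr[1]; d <- hdr[2]
    toks <- character(V)
    vecs <- matrix(NA_real_, V, d)
    for (i in seq_len(V)) {
      chars <- character(0)
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L) fail("unexpected end of file reading token %d", i)
        if (ch == " ") break
        if (ch == "\n" && length(chars) == 0L) next  # leading newline from previous record
        chars <- c(chars, ch)
      }
      toks[i] <- paste(chars, collapse = "")
      v <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
      if (length(v) != d) fail("unexpected end of file in vector for token %s", toks[i])
      vecs[i, ] <- v
    }
  }
  if (anyDuplicated(toks)) {
    dup <- duplicated(toks)
    warning(sprintf("duplicate embedding tokens (%s); keeping first occurrence",
                    paste(unique(toks[dup]), collapse = ", ")), call. = FALSE)
    toks <- toks[!dup]
    vecs <- vecs[!dup, , drop = FALSE]
  }
  embedding_table(toks, vecs)
}

#' Write an embedding table in word2vec format
#'
#' @param table An [embedding_table()].
#' @inheritParams load_embeddings
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(table, path,
                             format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  V <- length(table$tokens); d <- table$dim
  if (format == "word2vec-text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", V, d), con)
    for (i in seq_len(V)) {
      writeLines(paste(table$tokens[i],
                       paste(formatC(table$vectors[i, ], format = "g", digits = 17),
                             collapse = " ")), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("%d %d\n", V, d), con, eos = NULL)
    for (i in seq_len(V)) {
      writeChar(paste0(table$tokens[i], " "), con, eos = NULL)
      writeBin(as.numeric(table$vectors[i, ]), con, size = 4L, endian = "little")
      writeChar("\n", con, eos = NULL)
    }
  }
  invisible(path)
}

#' Random unit-norm embedding table
#'
#' Gaussian rows normalised to unit length; used by the synthetic-corpus
#' generator. Deterministic given `seed`.
#'
#' @param tokens Vocabulary tokens.
#' @param dim Embedding dimension.
#' @param seed Integer seed.
#' @return An [embedding_table()].
#' @export
random_embeddings <- function(tokens, dim, seed = 1L) {
  V <- length(tokens)
  vecs <- with_seed(seed, matrix(rnorm(V * dim), V, dim))
  vecs <- vecs / sqrt(rowSums(vecs^2))
  embedding_table(tokens, vecs)
}
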
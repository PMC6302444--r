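## Citation corpora: construction, JSON I/O, tokenization, label space.

#' Construct a citation record
#'
#' A citation is one biomedical record: the journal it appeared in, its title
#' and abstract, and the set of gold labels (MeSH descriptor names, or
#' synthetic label ids). At least one of title/abstract must be non-empty.
#'
#' @param journal Journal name (character scalar; may be empty).
#' @param title Title text.
#' @param abstract Abstract text.
#' @param labels Character vector of label identifiers; duplicates are an error.
#' @return An object of class `citation_record`.
#' @export
#' @examples
#' citation_record("J Test", "A title", "An abstract.", c("Humans", "Mice"))
citation_record <- function(journal = "", title = "", abstract = "", labels = character()) {
  journal <- as.character(journal)[1]
  title <- as.character(title)[1]
  abstract <- as.character(abstract)[1]
  labels <- as.character(labels)
  if (is.na(title)) title <- ""
  if (is.na(abstract)) abstract <- ""
  if (is.na(journal)) journal <- ""
  if (!nzchar(title) && !nzchar(abstract)) {
    fail("citation must have a non-empty title or abstract")
  }
  if (anyDuplicated(labels)) {
    fail("citation labels must form a set (duplicates: %s)",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(list(journal = journal, title = title, abstract = abstract,
                 labels = labels),
            class = "citation_record")
}

#' @export
print.citation_record <- function(x, ...) {
  cat("<citation> ", substr(x$title, 1, 60),
      if (nchar(x$title) > 60) "..." else "", "\n", sep = "")
  cat("  journal: ", x$journal, "\n", sep = "")
  cat("  abstract: ", nchar(x$abstract), " chars; labels: ",
      length(x$labels), "\n", sep = "")
  invisible(x)
}

## Field-name mapping for the BioASQ Task A JSON dialect; other dialects are
## handled by passing a modified mapping, never by code changes.
#' @export
#' @rdname load_citations
bioasq_fields <- function(journal = "journal", title = "title",
                          abstract = "abstractText", labels = "meshMajor") {
  list(journal = journal, title = title, abstract = abstract, labels = labels)
}

#' Read a citation corpus from JSON
#'
#' Reads BioASQ-Task-A-style records from either a JSON array of objects
#' (`format = "json"`) or one JSON object per line (`format = "jsonl"`).
#' Label strings are preserved verbatim. Field names follow the BioASQ
#' convention (`journal`/`title`/`abstractText`/`meshMajor`) and can be
#' remapped through `fields`.
#'
#' @param path Path to the corpus file.
#' @param format `"json"` (array) or `"jsonl"` (one record per line).
#' @param fields Field-name mapping, see [bioasq_fields()].
#' @return A list of [citation_record()] objects, class `citation_corpus`.
#' @export
load_citations <- function(path, format = c("json", "jsonl"),
                           fields = bioasq_fields()) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("corpus file not found: %s", path)
  records <- if (format == "json") {
    out <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                    error = function(e) fail("malformed JSON in %s: %s", path, conditionMessage(e)))
    if (!is.list(out)) fail("expected a JSON array of records in %s", path)
    out
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
               error = function(e) fail("malformed JSON at line %d of %s: %s",
                                        i, path, conditionMessage(e)))
    })
  }
  corpus <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    grab <- function(key, default) {
      v <- r[[key]]
      if (is.null(v)) default else v
    }
    title <- as.character(grab(fields$title, ""))
    abstract <- as.character(grab(fields$abstract, ""))
    if (!nzchar(paste0(title, collapse = "")) &&
        !nzchar(paste0(abstract, collapse = ""))) {
      fail("record %d in %s has neither title nor abstract", i, path)
    }
    labels <- unlist(grab(fields$labels, character()), use.names = FALSE)
    citation_record(journal = as.character(grab(fields$journal, "")),
                    title = title, abstract = abstract,
                    labels = unique(as.character(labels)))
  })
  structure(corpus, class = c("citation_corpus", "list"))
}

#' Write a citation corpus as BioASQ-style JSON
#'
#' Inverse of [load_citations()]; a written corpus reloads element-wise equal.
#'
#' @param corpus List of citations.
#' @inheritParams load_citations
#' @return `path`, invisibly.
#' @export
write_citations <- function(corpus, path, format = c("json", "jsonl"),
                            fields = bioasq_fields()) {
  format <- match.arg(format)
  recs <- lapply(corpus, function(cit) {
    r <- list()
    r[[fields$journal]] <- cit$journal
    r[[fields$title]] <- cit$title
    r[[fields$abstract]] <- cit$abstract
    r[[fields$labels]] <- as.list(cit$labels)
    r
  })
  if (format == "json") {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    lines <- vapply(recs, function(r) {
      as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' @export
print.citation_corpus <- function(x, ...) {
  nl <- lengths(lapply(x, `[[`, "labels"))
  cat("<citation_corpus> ", length(x), " citations, ",
      length(unique(unlist(lapply(x, `[[`, "labels")))), " distinct labels, ",
      "mean cardinality ", round(mean(nl), 2), "\n", sep = "")
  invisible(x)
}

#' Tokenize citation text
#'
#' Lowercases and splits on runs of non-alphanumeric characters; title tokens
#' precede abstract tokens. The journal name is not part of the token stream.
#'
#' @param citation A [citation_record()].
#' @return Character vector of tokens (possibly empty).
#' @export
tokenize_citation <- function(citation) {
  txt <- tolower(paste(citation$title, citation$abstract))
  toks <- strsplit(txt, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Encode a citation as a masked fixed-length index sequence
#'
#' Tokens are looked up in the embedding table; out-of-vocabulary tokens map
#' to a dedicated all-zero embedding row but stay mask-valid, preserving
#' sequence positions. Sequences longer than `max_len` are truncated to their
#' first `max_len` tokens; shorter ones are right-padded. The default
#' `max_len` of 360 words matches the preprocessing used for MEDLINE
#' citations.
#'
#' @param citation A [citation_record()].
#' @param table An [embedding_table()].
#' @param max_len Fixed sequence length (default 360).
#' @return A `padded_sequence`: list with integer `indices` (length
#'   `max_len`; `0` denotes the OOV/padding embedding row), logical `mask`
#'   (TRUE = real token), and `n_tokens` (original token count).
#' @export
tokenize_and_encode <- function(citation, table, max_len = 360L) {
  stopifnot(is_count(max_len))
  max_len <- as.integer(max_len)
  toks <- tokenize_citation(citation)
  n <- length(toks)
  if (n == 0L) {
    warning("citation produced an empty token stream; sequence is all padding",
            call. = FALSE)
  }
  kept <- head(toks, max_len)
  idx <- match(kept, table$tokens)      # NA = out of vocabulary
  idx[is.na(idx)] <- 0L                 # 0 indexes the zero OOV row
  n_valid <- length(kept)
  indices <- c(idx, rep.int(0L, max_len - n_valid))
  mask <- c(rep(TRUE, n_valid), rep(FALSE, max_len - n_valid))
  structure(list(indices = as.integer(indices), mask = mask, n_tokens = n),
            class = "padded_sequence")
}

#' Build a deterministic label space from a corpus
#'
#' Collects the distinct labels across citations and orders them
#' lexicographically (C locale), so the mapping label <-> column position is
#' invariant to corpus order.
#'
#' @param citations List of citations (or a `citation_corpus`).
#' @return A `label_space`: list with `labels` (ordered character vector) and
#'   `index` (named integer vector, positions `1..M`).
#' @export
build_label_space <- function(citations) {
  if (length(citations) == 0L) fail("need at least one citation")
  labs <- sort_c(unique(unlist(lapply(citations, `[[`, "labels"), use.names = FALSE)))
  label_space(labs)
}

#' @export
#' @rdname build_label_space
#' @param labels Ordered character vector of distinct labels.
label_space <- function(labels) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) fail("label space entries must be distinct")
  idx <- seq_along(labels)
  names(idx) <- labels
  structure(list(labels = labels, index = idx), class = "label_space")
}

#' @export
print.label_space <- function(x, ...) {
  cat("<label_space> M = ", length(x$labels), ": ",
      paste(head(x$labels, 5), collapse = ", "),
      if (length(x$labels) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Binary label matrix and label counts for a corpus
#'
#' @param corpus List of citations.
#' @param space A `label_space`.
#' @return List with `y` (n x M 0/1 matrix) and `z` (integer label counts,
#'   `z[i] == sum(y[i, ])`).
#' @export
label_matrix <- function(corpus, space) {
  n <- length(corpus)
  M <- length(space$labels)
  y <- matrix(0, n, M)
  for (i in seq_len(n)) {
    j <- space$index[corpus[[i]]$labels]
    if (anyNA(j)) {
      fail("citation %d carries labels outside the label space: %s", i,
           paste(setdiff(corpus[[i]]$labels, space$labels), collapse = ", "))
    }
    y[i, j] <- 1
  }
  list(y = y, z = as.integer(rowSums(y)))
}

#' Encode a whole corpus into stacked index/mask matrices
#'
#' Convenience wrapper around [tokenize_and_encode()] producing the dense
#' inputs the network consumes.
#'
#' @inheritParams tokenize_and_encode
#' @param corpus List of citations.
#' @param space Optional `label_space`; when supplied, gold label matrix and
#'   counts are attached.
#' @return An `encoded_corpus`: list with `idx` (n x L integer), `mask`
#'   (n x L logical), `lengths`, and, with `space`, `y` and `z`.
#' @export
encode_corpus <- function(corpus, table, max_len = 360L, space = NULL) {
  n <- length(corpus)
  max_len <- as.integer(max_len)
  idx <- matrix(0L, n, max_len)
  msk <- matrix(FALSE, n, max_len)
  lens <- integer(n)
  for (i in seq_len(n)) {
    ps <- tokenize_and_encode(corpus[[i]], table, max_len)
    idx[i, ] <- ps$indices
    msk[i, ] <- ps$mask
    lens[i] <- ps$n_tokens
  }
  out <- list(idx = idx, mask = msk, lengths = lens, max_len = max_len)
  if (!is.null(space)) {
    lm <- label_matrix(corpus, space)
    out$y <- lm$y
    out$z <- lm$z
    out$labels <- space$labels
  }
  structure(out, class = "encoded_corpus")
}
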
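## Synthetic desk-scale corpora with the statistical structure of the MeSH
## indexing task: Zipf-unbalanced label frequencies, ~13 labels per citation,
## and word-label dependence through a label->topic->word generative story.

#' Synthetic corpus configuration
#'
#' Defaults define the reference desk-scale corpus: 2,000 citations, a
#' 5,000-word vocabulary, 50 labels with Zipf exponent 1.1, a mean label
#' cardinality of 13 (the corpus-average MeSH count per MEDLINE citation),
#' and documents of ~120 words (capped at 360, the model's default sequence
#' length). Each label owns a latent topic; words are drawn from the topics
#' of the citation's labels plus uniform noise.
#'
#' @param n_citations Number of citations.
#' @param vocab_size Vocabulary size V.
#' @param n_labels Number of labels M.
#' @param zipf_exponent Zipf exponent s > 0 of the label-frequency law.
#' @param mean_labels_per_citation Mean label cardinality (must be < M);
#'   counts are 1 + Poisson(mean - 1), so every citation has at least one
#'   label.
#' @param doc_length_mean,doc_length_max Document length distribution
#'   (1 + Poisson(mean - 1), truncated at the maximum).
#' @param topic_count Number of latent topics; labels map to topics
#'   round-robin (default: one topic per label).
#' @param noise_rate Probability that a word is uniform noise rather than
#'   drawn from a label's topic.
#' @param embedding_dim Dimension of the generated random embedding table.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_citations = 2000L, vocab_size = 5000L,
                             n_labels = 50L, zipf_exponent = 1.1,
                             mean_labels_per_citation = 13,
                             doc_length_mean = 120L, doc_length_max = 360L,
                             topic_count = n_labels, noise_rate = 0.1,
                             embedding_dim = 50L, seed = 1L) {
  stopifnot(is_count(n_citations), is_count(vocab_size), is_count(n_labels),
            zipf_exponent > 0, mean_labels_per_citation >= 1,
            is_count(doc_length_mean), is_count(doc_length_max),
            is_count(topic_count), noise_rate >= 0, noise_rate <= 1,
            is_count(embedding_dim))
  if (mean_labels_per_citation >= n_labels) {
    fail("mean_labels_per_citation (%g) must be smaller than n_labels (%d)",
         mean_labels_per_citation, n_labels)
  }
  if (topic_count > vocab_size) fail("need at least one vocabulary word per topic")
  structure(list(n_citations = as.integer(n_citations),
                 vocab_size = as.integer(vocab_size),
                 n_labels = as.integer(n_labels),
                 zipf_exponent = zipf_exponent,
                 mean_labels_per_citation = mean_labels_per_citation,
                 doc_length_mean = as.integer(doc_length_mean),
                 doc_length_max = as.integer(doc_length_max),
                 topic_count = as.integer(topic_count),
                 noise_rate = noise_rate,
                 embedding_dim = as.integer(embedding_dim),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Zipf rank-frequency law
#'
#' `p_j` proportional to `j^(-s)`, normalised to sum to one; strictly
#' decreasing in rank. Models the extreme label imbalance of MeSH, where the
#' most frequent descriptor appears in millions of citations and mid-tail
#' descriptors in a handful.
#'
#' @param M Number of ranks (labels).
#' @param s Exponent, s > 0.
#' @return Probability vector of length M.
#' @export
zipf_frequencies <- function(M, s) {
  stopifnot(is_count(M), s > 0)
  w <- seq_len(M)^(-s)
  w / sum(w)
}

## Per-topic word distribution over that topic's vocabulary block: mildly
## Zipfish within the block so frequent keywords exist.
topic_word_blocks <- function(V, topic_count) {
  block <- floor(V / topic_count)
  lapply(seq_len(topic_count), function(t) {
    words <- ((t - 1L) * block + 1L):(t * block)
    w <- seq_along(words)^(-1)
    list(words = words, prob = w / sum(w))
  })
}

#' Generate a synthetic citation corpus
#'
#' Each label is assigned to a latent topic (round-robin). For each citation:
#' a label count is drawn as 1 + Poisson(mean - 1), that many distinct labels
#' are drawn without replacement with Zipf probabilities, and each word picks
#' one of the citation's labels uniformly and then a word from that label's
#' topic distribution — or, with probability `noise_rate`, a uniform random
#' word. The first ten words form the title, the rest the abstract. The
#' embedding table is Gaussian with unit-norm rows.
#'
#' @param config A [synthetic_config()].
#' @return List with `corpus` (a `citation_corpus`), `embeddings` (an
#'   [embedding_table()]), `space` (the `label_space`) and `config`.
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  V <- config$vocab_size; M <- config$n_labels
  vocab <- sprintf("w%05d", seq_len(V))
  labels <- sprintf("L%04d", seq_len(M))   # lexicographic == rank order
  journals <- sprintf("Synthetic Journal %d", 1:5)
  zipf <- zipf_frequencies(M, config$zipf_exponent)
  label_topic <- ((seq_len(M) - 1L) %% config$topic_count) + 1L
  topics <- topic_word_blocks(V, config$topic_count)
  corpus <- with_seed(config$seed, {
    lapply(seq_len(config$n_citations), function(i) {
      k <- min(1L + rpois(1L, config$mean_labels_per_citation - 1), M)
      labs <- sort(sample.int(M, k, prob = zipf))
      len <- min(1L + rpois(1L, config$doc_length_mean - 1L), config$doc_length_max)
      lab_for_word <- labs[sample.int(k, len, replace = TRUE)]
      words <- vapply(lab_for_word, function(l) {
        tp <- topics[[label_topic[l]]]
        sample(tp$words, 1L, prob = tp$prob)
      }, integer(1))
      noisy <- runif(len) < config$noise_rate
      words[noisy] <- sample.int(V, sum(noisy), replace = TRUE)
      toks <- vocab[words]
      n_title <- min(10L, len)
      citation_record(journal = sample(journals, 1L),
                      title = paste(toks[seq_len(n_title)], collapse = " "),
                      abstract = if (len > n_title)
                        paste(toks[(n_title + 1L):len], collapse = " ") else "",
                      labels = labels[labs])
    })
  })
  class(corpus) <- c("citation_corpus", "list")
  list(corpus = corpus,
       embeddings = random_embeddings(vocab, config$embedding_dim,
                                      seed = config$seed + 1L),
       space = label_space(labels),
       config = config)
}

#' Learnability probe for a synthetic corpus
#'
#' Confirms the corpus carries non-trivial word-label signal before it is
#' used to exercise training. The corpus is split in half deterministically
#' (odd positions fit, even positions evaluate); a nearest-centroid baseline
#' (cosine similarity between a held-out citation's bag-of-words vector and
#' per-label centroids fitted on the other half, top-k with k = round(mean
#' cardinality)) is compared against the prior-only baseline that always
#' predicts the k most frequent fitted labels. With real signal the centroid
#' probe clearly beats the prior; at noise rate 1 the two coincide up to
#' sampling error. The held-out split matters: centroids scored on their own
#' fitting documents would look informative even for pure noise.
#'
#' @param corpus A `citation_corpus` (at least two citations).
#' @param space The corresponding `label_space`.
#' @return List with `probe` and `prior` (micro-P/R/F vectors on the held-out
#'   half), `k`, and `signal` (probe F minus prior F).
#' @export
learnability_probe <- function(corpus, space) {
  M <- length(space$labels)
  n <- length(corpus)
  if (n < 2L) fail("learnability_probe needs at least two citations")
  tok_sets <- lapply(corpus, tokenize_citation)
  vocab <- sort_c(unique(unlist(tok_sets)))
  V <- length(vocab)
  tf <- matrix(0, n, V)
  for (i in seq_len(n)) {
    tab <- table(match(tok_sets[[i]], vocab))
    tf[i, as.integer(names(tab))] <- as.integer(tab)
  }
  lm <- label_matrix(corpus, space)
  fit_ids <- seq(1L, n, by = 2L)
  eval_ids <- seq(2L, n, by = 2L)
  gold <- apply(lm$y[eval_ids, , drop = FALSE], 1L, function(r) which(r > 0),
                simplify = FALSE)
  k <- max(1L, round_half_away(mean(lm$z[fit_ids])))
  ## prior baseline: k most frequent labels of the fitting half
  freq_order <- order(-colSums(lm$y[fit_ids, , drop = FALSE]), seq_len(M))
  prior_set <- sort(freq_order[seq_len(k)])
  prior <- micro_prf(rep(list(prior_set), length(eval_ids)), gold)
  ## centroid probe: cosine similarity to per-label mean tf vectors
  yfit <- lm$y[fit_ids, , drop = FALSE]
  centroids <- crossprod(yfit, tf[fit_ids, , drop = FALSE]) /
    pmax(colSums(yfit), 1)                       # M x V
  cnorm <- sqrt(rowSums(centroids^2))
  tfe <- tf[eval_ids, , drop = FALSE]
  dnorm <- sqrt(rowSums(tfe^2))
  sims <- tfe %*% t(centroids) / (pmax(dnorm, 1e-12) %o% pmax(cnorm, 1e-12))
  probe_sets <- lapply(seq_len(nrow(sims)), function(i)
    sort(order(-sims[i, ], seq_len(M))[seq_len(k)]))
  probe <- micro_prf(probe_sets, gold)
  list(probe = probe, prior = prior, k = k,
       signal = unname(probe[["f_measure"]] - prior[["f_measure"]]))
}

#' Write a synthetic corpus to disk
#'
#' Emits the citation JSON (BioASQ dialect) and the embedding table in
#' word2vec text format, so the files round-trip through [load_citations()]
#' and [load_embeddings()].
#'
#' @param sim Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus_path <- file.path(dir, "corpus.json")
  emb_path <- file.path(dir, "embeddings.txt")
  write_citations(sim$corpus, corpus_path, format = "json")
  write_embeddings(sim$embeddings, emb_path, format = "word2vec-text")
  invisible(c(corpus = corpus_path, embeddings = emb_path))
}
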
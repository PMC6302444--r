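test_that("citation records enforce their invariants", {
  expect_error(citation_record("J", "", "", "A"), "non-empty title or abstract")
  expect_error(citation_record("J", "t", "a", c("A", "A")), "duplicates")
  cit <- citation_record("J", "Only a title", "", c("B", "A"))
  expect_identical(cit$labels, c("B", "A"))
  expect_identical(cit$abstract, "")
})

test_that("BioASQ-style JSON loads with labels preserved verbatim", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines(paste0(
    '[{"journal":"J One","title":"First title","abstractText":"Body one.",',
    '"meshMajor":["Humans","Mice, Inbred BALB C"]},',
    '{"journal":"J Two","title":"Second title",',
    '"meshMajor":["Humans"]}]'), path)
  corpus <- load_citations(path)
  expect_length(corpus, 2L)
  expect_identical(corpus[[1]]$labels, c("Humans", "Mice, Inbred BALB C"))
  expect_identical(corpus[[2]]$abstract, "")  # missing key -> empty abstract
  expect_identical(corpus[[2]]$journal, "J Two")
})

test_that("malformed and invalid records give informative errors", {
  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"title":"ok","meshMajor":[]}', '{"title": oops'), bad)
  expect_error(load_citations(bad, format = "jsonl"), "line 2")
  noboth <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"journal":"J","meshMajor":["A"]}]', noboth)
  expect_error(load_citations(noboth), "neither title nor abstract")
})

test_that("a generated corpus survives a write/read round trip", {
  sim <- tiny_sim(seed = 11)
  for (fmt in c("json", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_citations(sim$corpus, path, format = fmt)
    back <- load_citations(path, format = fmt)
    expect_length(back, length(sim$corpus))
    for (i in seq_along(back)) {
      expect_identical(unclass(back[[i]]), unclass(sim$corpus[[i]]))
    }
  }
})

test_that("tokenization lowercases, splits on non-alphanumerics, title first", {
  cit <- citation_record("J", "Alpha-beta GAMMA", "delta42, (epsilon)", "L")
  expect_identical(tokenize_citation(cit),
                   c("alpha", "beta", "gamma", "delta42", "epsilon"))
})

test_that("encoding truncates to the first max_len tokens and pads the rest", {
  table <- embedding_table(c("tok"), matrix(0.5, 1, 4))
  long <- citation_record("J", paste(rep("tok", 40), collapse = " "),
                          paste(rep("tok", 360), collapse = " "), "L")
  ps <- tokenize_and_encode(long, table, max_len = 360L)
  expect_length(ps$indices, 360L)
  expect_identical(sum(ps$mask), 360L)      # 400 tokens -> full valid window
  expect_identical(ps$n_tokens, 400L)
  short <- citation_record("J", paste(rep("tok", 10), collapse = " "), "", "L")
  ps2 <- tokenize_and_encode(short, table, max_len = 360L)
  expect_identical(sum(ps2$mask), 10L)
  expect_true(all(!ps2$mask[11:360]))
  expect_true(all(ps2$indices[11:360] == 0L))
})

test_that("OOV tokens stay mask-valid and map to the zero row", {
  table <- embedding_table(c("known"), matrix(1, 1, 3))
  cit <- citation_record("J", "strange words only", "", "L")
  ps <- tokenize_and_encode(cit, table, max_len = 5L)
  expect_identical(sum(ps$mask), 3L)
  expect_true(all(ps$indices[1:3] == 0L))
  expect_identical(lookup_embedding(table, "strange"), c(0, 0, 0))
})

test_that("an empty token stream warns and yields an all-padded sequence", {
  table <- embedding_table(c("x"), matrix(1, 1, 2))
  cit <- citation_record("J", "", "!!! ---", "L")  # punctuation only
  expect_warning(ps <- tokenize_and_encode(cit, table, max_len = 4L),
                 "empty token stream")
  expect_identical(sum(ps$mask), 0L)
})

test_that("encoding is deterministic", {
  sim <- tiny_sim(seed = 3)
  e1 <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20)
  e2 <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20)
  expect_identical(e1$idx, e2$idx)
  expect_identical(e1$mask, e2$mask)
})

test_that("label space is sorted, gapless, and corpus-order invariant", {
  cits <- list(citation_record("J", "t", "", "B"),
               citation_record("J", "t", "", c("A", "B")))
  sp <- build_label_space(cits)
  expect_identical(sp$labels, c("A", "B"))
  expect_identical(unname(sp$index), 1:2)
  disjoint <- list(citation_record("J", "t", "", c("C", "D")),
                   citation_record("J", "t", "", c("A", "B")))
  expect_length(build_label_space(disjoint)$labels, 4L)
  sim <- tiny_sim(seed = 5)
  sp1 <- build_label_space(sim$corpus)
  sp2 <- build_label_space(rev(sim$corpus))
  expect_identical(sp1$labels, sp2$labels)
  expect_error(build_label_space(list()), "at least one")
})

test_that("label matrix ties counts to row sums", {
  sim <- tiny_sim(seed = 9)
  lm <- label_matrix(sim$corpus, sim$space)
  expect_identical(lm$z, as.integer(rowSums(lm$y)))
  expect_true(all(lm$y %in% c(0, 1)))
  expect_true(all(lm$z >= 1L))
})
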
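test_that("initialisation zeroes every bias and respects the Xavier bound", {
  sim <- tiny_sim(seed = 2)
  params <- init_params(tiny_model_cfg(), sim$embeddings, seed = 5)
  expect_identical(params$dense1$b, numeric(10))
  expect_identical(params$dense2$b, numeric(10))
  expect_identical(params$out$b, numeric(6))
  # large layer: empirical bound and near-zero mean
  set.seed(1)
  W <- xavier_matrix(100, 100)
  bound <- sqrt(6 / 200)
  expect_true(all(abs(W) <= bound))
  expect_lt(abs(mean(W)), bound / 10)
  # GRU weights obey their own fan-in/fan-out bound
  bz <- sqrt(6 / (5 + 10))
  expect_true(all(abs(params$gru_f$Wz) <= bz))
})

test_that("the same seed reproduces parameters bit for bit", {
  sim <- tiny_sim(seed = 2)
  p1 <- init_params(tiny_model_cfg(), sim$embeddings, seed = 42)
  p2 <- init_params(tiny_model_cfg(), sim$embeddings, seed = 42)
  expect_identical(p1$gru_f$Wc, p2$gru_f$Wc)
  expect_identical(p1$dense1$W, p2$dense1$W)
  expect_identical(p1$out$W, p2$out$W)
})

test_that("forward produces the serial identity R = sum(P) in both modes", {
  sim <- tiny_sim(seed = 13)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(), sim$embeddings, seed = 3)
  for (mode in c("inference", "train")) {
    fw <- model_forward(params, enc$idx[1:16, ], enc$mask[1:16, ], mode)
    expect_lt(max(abs(fw$R - rowSums(fw$P))), 1e-6)
    expect_true(all(fw$P > 0 & fw$P < 1))
    expect_true(all(fw$R >= 0 & fw$R <= 6))
  }
})

test_that("inference is a pure function and duplicates get identical outputs", {
  sim <- tiny_sim(seed = 17)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(), sim$embeddings, seed = 8)
  ids <- c(1, 2, 1, 3)  # row 3 duplicates row 1
  fw1 <- model_forward(params, enc$idx[ids, ], enc$mask[ids, ], "inference")
  fw2 <- model_forward(params, enc$idx[ids, ], enc$mask[ids, ], "inference")
  expect_identical(fw1$P, fw2$P)
  expect_identical(fw1$P[1, ], fw1$P[3, ])
  expect_identical(fw1$R[1], fw1$R[3])
})

test_that("hidden layers have the configured representation width", {
  sim <- tiny_sim(seed = 19)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(), sim$embeddings, seed = 2)
  fw <- model_forward(params, enc$idx[1:4, ], enc$mask[1:4, ], "train",
                      keep_cache = TRUE)
  expect_identical(ncol(fw$H), 10L)          # 2 * hidden_dim
  expect_identical(ncol(fw$cache$b1$y), 10L) # first dense layer width
  expect_identical(ncol(fw$cache$b2$y), 10L) # second dense layer width
  expect_identical(dim(fw$P), c(4L, 6L))
})

test_that("count_labels is the all-ones dot product with a domain guard", {
  expect_identical(count_labels(c(0.2, 0.3, 0.5)), 1.0)
  expect_identical(count_labels(numeric(10)), 0)
  expect_identical(count_labels(rep(1, 28472)), 28472)
  expect_error(count_labels(c(0.5, 1.2)), "\\[0, 1\\]")
  m <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_equal(count_labels(m), rowSums(m))
})

test_that("the parallel variant unties R from the probability sum", {
  sim <- tiny_sim(seed = 23)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(variant = "parallel"), sim$embeddings,
                        seed = 4)
  fw <- model_forward(params, enc$idx[1:10, ], enc$mask[1:10, ], "inference")
  expect_gt(max(abs(fw$R - rowSums(fw$P))), 1e-3)
})

test_that("the unidirectional variant halves the representation", {
  sim <- tiny_sim(seed = 29)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  cfg <- tiny_model_cfg(variant = "unidirectional")
  expect_identical(cfg$rep_dim, 5L)
  params <- init_params(cfg, sim$embeddings, seed = 4)
  expect_null(params$gru_b)
  fw <- model_forward(params, enc$idx[1:4, ], enc$mask[1:4, ], "inference")
  expect_identical(ncol(fw$H), 5L)
  expect_lt(max(abs(fw$R - rowSums(fw$P))), 1e-6)  # still serial
})

test_that("checkpoints round-trip parameters and predictions exactly", {
  sim <- tiny_sim(seed = 31)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(), sim$embeddings, seed = 12)
  params$labels <- sim$space$labels
  path <- withr::local_tempfile(fileext = ".json")
  save_model(params, path)
  back <- load_model(path)
  expect_identical(back$gru_f$Wz, params$gru_f$Wz)
  expect_identical(back$labels, sim$space$labels)
  fw1 <- model_forward(params, enc$idx[1:5, ], enc$mask[1:5, ], "inference")
  fw2 <- model_forward(back, enc$idx[1:5, ], enc$mask[1:5, ], "inference")
  expect_identical(fw1$P, fw2$P)
})
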
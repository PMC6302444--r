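# Training runs here use a deliberately small world (80 citations, 6 labels,
# 5 hidden units) so each fit takes about a second.

fit_tiny <- function(variant = "smtl", epochs = 4, seed = 1, sim = tiny_sim(seed = 201), ...) {
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  train_model(enc, sim$space, sim$embeddings,
              config = train_config(epochs = epochs, batch_size = 16,
                                    seed = seed, variant = variant,
                                    val_fraction = 0.2, ...),
              model_cfg = tiny_model_cfg(variant = variant))
}

test_that("history has one finite record per epoch and the loss decreases", {
  fit <- fit_tiny(epochs = 6)
  h <- fit$history
  expect_identical(nrow(h), 6L)
  expect_identical(h$epoch, 1:6)
  expect_true(all(is.finite(h$loss)))
  expect_true(all(is.finite(h$val_f)))
  expect_lt(h$loss_pri[6], h$loss_pri[1])
  expect_identical(h$loss, h$loss_pri + h$loss_aux)
})

test_that("training is bit-reproducible given the seed", {
  f1 <- fit_tiny(seed = 7)
  f2 <- fit_tiny(seed = 7)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$gru_f$Wc, f2$params$gru_f$Wc)
  expect_identical(f1$params$out$W, f2$params$out$W)
  expect_identical(f1$params$bn1$mean, f2$params$bn1$mean)
  f3 <- fit_tiny(seed = 8)
  expect_false(identical(f1$params$out$W, f3$params$out$W))
})

test_that("the plain variant optimises the classification loss alone", {
  fit <- fit_tiny(variant = "plain", lambda = 3)
  expect_true(all(fit$history$loss_aux == 0))
  expect_identical(fit$history$loss, fit$history$loss_pri)
})

test_that("auxiliary labels cannot influence plain-variant gradients", {
  sim <- tiny_sim(seed = 203)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(variant = "plain"), sim$embeddings, seed = 3)
  fw <- model_forward(params, enc$idx[1:8, ], enc$mask[1:8, ], "train",
                      keep_cache = TRUE)
  g1 <- smtl:::model_backward(params, fw, enc$y[1:8, ], enc$z[1:8])
  g2 <- smtl:::model_backward(params, fw, enc$y[1:8, ], enc$z[1:8] + 100)
  expect_identical(g1, g2)
})

test_that("variant assembly matches its structural contract", {
  sim <- tiny_sim(seed = 205)
  p_par <- build_variant("parallel_mtl", sim$space, sim$embeddings,
                         model_cfg = tiny_model_cfg(), seed = 2)
  expect_identical(p_par$config$variant, "parallel")
  expect_identical(dim(p_par$reg$W), c(1L, 10L))
  p_uni <- build_variant("unidirectional", sim$space, sim$embeddings,
                         model_cfg = tiny_model_cfg(), seed = 2)
  expect_null(p_uni$gru_b)
  expect_identical(p_uni$config$rep_dim, 5L)
  expect_error(build_variant("lstm", sim$space, sim$embeddings), "unknown variant")
})

test_that("early stopping truncates the history", {
  fit <- fit_tiny(epochs = 30, patience = 2, lr = 1e-5)  # tiny steps stall fast
  expect_lt(nrow(fit$history), 30L)
})

test_that("trainable embeddings change during training, frozen ones do not", {
  sim <- tiny_sim(seed = 207)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  frozen <- train_model(enc, sim$space, sim$embeddings,
                        config = train_config(epochs = 2, batch_size = 16,
                                              seed = 1, val_fraction = 0),
                        model_cfg = tiny_model_cfg())
  expect_identical(frozen$params$emb[-1, ], sim$embeddings$vectors)
  tuned <- train_model(enc, sim$space, sim$embeddings,
                       config = train_config(epochs = 2, batch_size = 16,
                                             seed = 1, val_fraction = 0),
                       model_cfg = tiny_model_cfg(trainable_embeddings = TRUE))
  expect_false(identical(tuned$params$emb[-1, ], sim$embeddings$vectors))
  expect_identical(tuned$params$emb[1, ], rep(0, 10))  # OOV row stays zero
})

test_that("a separable corpus is fit well beyond the prior baseline", {
  sim <- tiny_sim(seed = 209, n = 200, noise = 0)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  fit <- train_model(enc, sim$space, sim$embeddings,
                     config = train_config(epochs = 25, batch_size = 16, seed = 1,
                                           lr = 2e-3, val_fraction = 0),
                     model_cfg = model_config(n_labels = 6, embedding_dim = 10,
                                              max_len = 20, hidden_dim = 8,
                                              trainable_embeddings = TRUE))
  expect_lt(fit$history$loss_pri[25], prior_baseline_bce(enc$y))
  m <- evaluate_predictions(predict_corpus(fit$params, enc), enc)
  expect_gt(m[["f_measure"]], 0.6)
  expect_lt(m[["mse"]], var(enc$z))
})
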
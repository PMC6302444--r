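test_that("zero input and zero state are a fixed point of the cell", {
  p <- random_gru(4, 3, seed = 1)
  expect_identical(gru_step(numeric(4), numeric(3), p), c(0, 0, 0))
})

test_that("scalar cell with unit weights matches the closed form", {
  p <- structure(list(Wz = matrix(1), Uz = matrix(1), Wr = matrix(1),
                      Ur = matrix(1), Wc = matrix(1), Uc = matrix(1)),
                 class = "gru_params")
  h <- gru_step(1, 0, p)
  # z = sigmoid(1), candidate = tanh(1), h_prev = 0 -> h = sigmoid(1)*tanh(1)
  expect_equal(h, plogis(1) * tanh(1), tolerance = 1e-12)
  expect_equal(round(h, 4), 0.5568)
})

test_that("gru_step matches the straight-line scalar oracle on random cells", {
  set.seed(101)
  for (rep in 1:100) {
    d <- sample(1:8, 1); u <- sample(1:8, 1)
    p <- gru_params(d, u)
    x <- rnorm(d); h <- runif(u, -1, 1)
    expect_lt(max(abs(gru_step(x, h, p) - oracle_gru_step(x, h, p))), 1e-6)
  }
})

test_that("gates and states respect their ranges", {
  set.seed(55)
  p <- gru_params(6, 5)
  x_seq <- matrix(rnorm(12 * 6, sd = 3), 12, 6)
  res <- run_direction(x_seq, rep(TRUE, 12), p, "forward", return_states = TRUE)
  expect_true(all(res$states > -1 & res$states < 1))
  # gate values themselves: recompute one step's gates directly
  z <- 1 / (1 + exp(-(p$Wz %*% x_seq[1, ])))
  expect_true(all(z > 0 & z < 1))
})

test_that("masked runs ignore trailing padding entirely", {
  set.seed(77)
  p <- gru_params(3, 4)
  x <- matrix(rnorm(15), 5, 3)
  m <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  base <- run_direction(x[1:3, , drop = FALSE], rep(TRUE, 3), p, "forward")
  padded <- run_direction(x, m, p, "forward")
  expect_identical(base, padded)
  more <- rbind(x, matrix(rnorm(30), 10, 3))
  mm <- c(m, rep(FALSE, 10))
  expect_lt(max(abs(run_direction(more, mm, p, "forward") - base)), 1e-12)
  expect_lt(max(abs(run_direction(more, mm, p, "backward") -
                    run_direction(x, m, p, "backward"))), 1e-12)
})

test_that("an all-padded sequence returns the zero state with a warning", {
  p <- random_gru(2, 3, seed = 9)
  x <- matrix(rnorm(8), 4, 2)
  expect_warning(h <- run_direction(x, rep(FALSE, 4), p, "forward"),
                 "all-padded")
  expect_identical(h, c(0, 0, 0))
})

test_that("a non-trailing mask is rejected", {
  p <- random_gru(2, 2, seed = 2)
  x <- matrix(0, 3, 2)
  expect_error(run_direction(x, c(FALSE, TRUE, TRUE), p), "trailing-padded")
})

test_that("the backward direction equals a forward run on the reversed sequence", {
  set.seed(12)
  p <- gru_params(4, 3)
  x <- matrix(rnorm(24), 6, 4)
  m <- rep(TRUE, 6)
  expect_equal(run_direction(x, m, p, "backward"),
               run_direction(x[6:1, , drop = FALSE], m, p, "forward"))
})

test_that("bidirectional encoding concatenates the two final states", {
  set.seed(33)
  fwd <- gru_params(4, 3); bwd <- gru_params(4, 3)
  x <- matrix(rnorm(20), 5, 4)
  m <- rep(TRUE, 5)
  H <- bgru_encode(x, m, fwd, bwd)
  expect_length(H, 6L)
  expect_identical(H[1:3], run_direction(x, m, fwd, "forward"))
  # with shared weights, the backward half equals the forward half on the
  # reversed sequence
  H2 <- bgru_encode(x, m, fwd, fwd)
  expect_equal(H2[4:6],
               run_direction(x[5:1, , drop = FALSE], m, fwd, "forward"))
  expect_identical(bgru_encode(matrix(0, 5, 4), m, fwd, bwd), rep(0, 6))
})

test_that("run_direction agrees with the scalar-loop oracle over sequences", {
  set.seed(202)
  for (rep in 1:20) {
    d <- sample(1:6, 1); u <- sample(1:6, 1); L <- sample(1:12, 1)
    p <- gru_params(d, u)
    x <- matrix(rnorm(L * d), L, d)
    nv <- sample(0:L, 1)
    m <- c(rep(TRUE, nv), rep(FALSE, L - nv))
    got <- suppressWarnings(run_direction(x, m, p, "forward"))
    expect_lt(max(abs(got - oracle_run_forward(x, m, p))), 1e-6)
  }
})

test_that("the batched compiled encoder matches the single-sequence R path", {
  sim <- tiny_sim(seed = 21)
  enc <- encode_corpus(sim$corpus, sim$embeddings, max_len = 20, space = sim$space)
  params <- init_params(tiny_model_cfg(), sim$embeddings, seed = 6)
  fw <- model_forward(params, enc$idx[1:8, ], enc$mask[1:8, ], "inference")
  for (i in c(1, 4, 8)) {
    xs <- params$emb[enc$idx[i, ] + 1L, , drop = FALSE]
    ref <- suppressWarnings(bgru_encode(xs, enc$mask[i, ], params$gru_f, params$gru_b))
    expect_lt(max(abs(fw$H[i, ] - ref)), 1e-12)
  }
})
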
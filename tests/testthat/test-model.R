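test_that("pooling concatenates max, mean and last state in order", {
  h <- rbind(c(1, 2), c(3, 0), c(2, 2))
  out <- pool_states(h)
  expect_equal(unname(out[1:6]), c(3, 2, 2, 4 / 3, 2, 2))

  v <- c(0.5, -1, 2)
  single <- pool_states(matrix(v, 1))
  expect_equal(unname(single[1:9]), c(v, v, v))

  # max component dominates mean component coordinate-wise
  hs <- array(rnorm(5 * 7 * 4), dim = c(5, 7, 4))
  p <- pool_states(hs)
  expect_true(all(p[, 1:4] >= p[, 5:8] - 1e-12))
  expect_equal(ncol(p), 3 * 4)
})

test_that("embedding lookup honours PAD initialization and dropout limits", {
  m <- lncpair_model(vocab_size = 6, n_embedding = 4, n_hidden = 3, seed = 3)
  ids <- matrix(c(0L, 2L, 3L, 0L), 2, 2)
  X <- embed_tokens(m, ids)
  expect_equal(X[1, 1, ], rep(0, 4)) # PAD row is zero at init
  expect_identical(X, embed_tokens(m, ids)) # eval mode is deterministic

  m1 <- lncpair_model(vocab_size = 6, n_embedding = 4, n_hidden = 3,
                      p_embed_vector = 1, seed = 3)
  withr::with_seed(1, {
    Xdrop <- embed_tokens(m1, ids, training = TRUE)
  })
  expect_true(all(Xdrop == 0))
  expect_error(embed_tokens(m, matrix(9L, 1, 1)), "out of range")
})

test_that("inverted dropout preserves the eval-mode expectation (Monte Carlo)", {
  m <- lncpair_model(vocab_size = 6, n_embedding = 4, n_hidden = 3,
                     p_embed_vector = 0.3, p_embed_weight = 0, seed = 3)
  ids <- matrix(c(2L, 3L, 4L, 5L), 1, 4)
  ref <- embed_tokens(m, ids)
  n_mc <- 10000
  acc <- array(0, dim = dim(ref))
  withr::with_seed(99, {
    for (i in seq_len(n_mc)) acc <- acc + embed_tokens(m, ids, training = TRUE)
  })
  mc <- acc / n_mc
  # SE of a Bernoulli(1-p)/(1-p) mask is sqrt(p/(1-p))/sqrt(n) per entry
  se <- sqrt(0.3 / 0.7) / sqrt(n_mc) * abs(ref)
  expect_true(all(abs(mc - ref) <= 3 * se + 1e-12))
})

test_that("LSTM matches a hand-evaluated single step and zero fixed points", {
  # H = 1, d = 1: set every weight explicitly and evaluate the gate
  # equations by hand for x_1 = 0.8, h_0 = c_0 = 0.
  m <- lncpair_model(vocab_size = 4, n_embedding = 1, n_hidden = 1,
                     use_bias = FALSE, seed = 1)
  m$params$Wx <- matrix(c(0.5, -0.3, 0.9, 1.1), 1, 4) # i, f, o, c
  m$params$Uh <- matrix(c(0.2, 0.4, -0.6, 0.7), 1, 4)
  m$params$b <- rep(0, 4)
  x <- matrix(0.8, 1, 1)
  h <- lstm_forward(m, x)
  sig <- function(z) 1 / (1 + exp(-z))
  i1 <- sig(0.5 * 0.8); o1 <- sig(0.9 * 0.8); g1 <- tanh(1.1 * 0.8)
  c1 <- i1 * g1 # f gate multiplies c_0 = 0
  expect_equal(h[1, 1], o1 * tanh(c1), tolerance = 1e-12)

  # zero weights and inputs give all-zero hidden states
  mz <- m
  for (nm in c("Wx", "Uh", "b")) mz$params[[nm]][] <- 0
  hz <- lstm_forward(mz, matrix(0, 5, 1))
  expect_true(all(hz == 0))
})

test_that("DropConnect with p = 0 reproduces the plain LSTM bitwise", {
  m0 <- lncpair_model(vocab_size = 8, n_embedding = 4, n_hidden = 3,
                      p_dropconnect = 0, seed = 5)
  x <- array(rnorm(2 * 6 * 4), dim = c(2, 6, 4))
  expect_identical(lstm_forward(m0, x, training = TRUE),
                   lstm_forward(m0, x, training = FALSE))
})

test_that("batch normalization matches its closed form in both modes", {
  bn <- batch_norm(matrix(c(1, 3), 2, 1), gamma = 1, beta = 0,
                   running_mean = 0, running_var = 1, training = TRUE)
  expect_equal(bn$y[, 1], c(-1, 1), tolerance = 1e-4) # eps-adjusted

  bn0 <- batch_norm(matrix(rnorm(10), 5, 2), gamma = c(0, 0), beta = c(2, -1),
                    running_mean = c(0, 0), running_var = c(1, 1),
                    training = TRUE)
  expect_true(all(bn0$y[, 1] == 2 & bn0$y[, 2] == -1))

  x <- matrix(rnorm(200), 50, 4)
  bnt <- batch_norm(x, rep(1, 4), rep(0, 4), rep(0, 4), rep(1, 4),
                    training = TRUE)
  expect_true(all(abs(colMeans(bnt$y)) < 1e-12))
  biased_var <- function(z) mean((z - mean(z))^2)
  expect_equal(apply(bnt$y, 2, biased_var), rep(1, 4), tolerance = 1e-4)

  expect_error(batch_norm(matrix(1, 1, 2), c(1, 1), c(0, 0), c(0, 0), c(1, 1),
                          training = TRUE), "batch size >= 2")

  # eval mode normalizes by the running statistics, untouched by the batch
  bne <- batch_norm(x, rep(1, 4), rep(0, 4), c(1, 1, 1, 1), c(4, 4, 4, 4),
                    training = FALSE)
  expect_equal(bne$y, (x - 1) / sqrt(4 + 1e-5), ignore_attr = TRUE)
})

test_that("forward pass yields probability rows and is reproducible in eval mode", {
  m <- lncpair_model(vocab_size = 20, n_embedding = 6, n_hidden = 5,
                     n_dense = 4, seed = 11)
  ids <- matrix(sample(0:19, 8 * 10, replace = TRUE), 8, 10)
  p1 <- predict_proba(m, ids)
  expect_true(all(abs(rowSums(p1) - 1) < 1e-6))
  expect_true(all(p1 >= 0))
  expect_identical(p1, predict_proba(m, ids))
})

test_that("analytic gradients match central finite differences everywhere", {
  m <- gradcheck_model()
  withr::with_seed(42, {
    ids <- matrix(sample(0:7, 4 * 6, replace = TRUE), 4, 6)
  })
  labels <- c(0L, 1L, 1L, 0L)
  an <- model_loss_grads(m, ids, labels)
  for (nm in names(an$grads)) {
    expect_lt(max_rel_err(numeric_grad(m, nm, ids, labels), an$grads[[nm]]),
              1e-4)
  }
})

test_that("parameter count matches the closed-form formula and grows with H", {
  V <- 6L; d <- 2L; H <- 2L; D <- 3L
  m <- lncpair_model(V, d, H, D, seed = 1)
  expected <- V * d +                       # embedding
    4 * (d * H + H * H) + 4 * H +           # LSTM gates + biases
    2 * (3 * H) +                           # batch norm 1
    (3 * H * D + D) +                       # dense 1
    2 * D +                                 # batch norm 2
    (D * 2 + 2)                             # dense 2
  expect_equal(count_parameters(m), expected)
  m2 <- lncpair_model(V, d, 2 * H, D, seed = 1)
  expect_gt(count_parameters(m2), count_parameters(m))
  m_nb <- lncpair_model(V, d, H, D, use_bias = FALSE, seed = 1)
  expect_equal(count_parameters(m_nb), expected - 4 * H)
})
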
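test_that("AdamW with zero decay reduces to plain Adam (independent oracle)", {
  params <- list(w = matrix(c(1, -2, 0.5, 3), 2, 2))
  grads <- list(w = matrix(c(0.1, -0.4, 0.2, -0.1), 2, 2))
  st <- adamw_init(params)
  # independent plain-Adam implementation
  m <- v <- matrix(0, 2, 2)
  w <- params$w
  for (t in 1:3) {
    g <- grads$w * t
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    w <- w - 0.01 * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.999^t)) + 1e-8)
    step <- adamw_step(params, list(w = g), st, lr = 0.01, weight_decay = 0)
    params <- step$params; st <- step$state
  }
  expect_identical(params$w, w)
})

test_that("a scalar AdamW step matches the hand-evaluated decoupled update", {
  params <- list(w = 1)
  grads <- list(w = 0.5)
  step <- adamw_step(params, grads, adamw_init(params), lr = 0.01,
                     weight_decay = 0.02)
  # by hand: m_hat = g, v_hat = g^2 at t = 1 (bias correction exact), so the
  # adaptive step is lr * g / (|g| + eps); decay subtracts lr * lambda * w
  expected <- 1 - 0.01 * 0.5 / (0.5 + 1e-8) - 0.01 * 0.02 * 1
  expect_equal(step$params$w, expected, tolerance = 1e-12)
})

test_that("decoupled decay differs from L2-folded decay under adaptive scaling", {
  # two parameters with very different gradient magnitudes
  params <- list(w = c(1, 1))
  g <- c(1, 0.01)
  lam <- 0.1
  dec <- adamw_step(params, list(w = g), adamw_init(params), lr = 0.1,
                    weight_decay = lam)$params$w
  l2 <- adamw_step(params, list(w = g + 2 * lam * params$w),
                   adamw_init(params), lr = 0.1, weight_decay = 0)$params$w
  expect_gt(max(abs(dec - l2)), 1e-4)
})

test_that("non-finite gradients are rejected with the tensor named", {
  params <- list(a = 1, b = 2)
  expect_error(
    adamw_step(params, list(a = 0.1, b = NaN), adamw_init(params), lr = 0.01),
    "tensor 'b'")
})

test_that("compute_metrics reproduces hand-computed confusion-matrix values", {
  perfect <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))
  expect_equal(unlist(perfect[c("ACC", "SPE", "SEN", "PRE", "F1", "MCC", "AUROC")]),
               c(ACC = 1, SPE = 1, SEN = 1, PRE = 1, F1 = 1, MCC = 1, AUROC = 1))
  expect_equal(perfect$undefined, "")

  # TP=40 TN=30 FP=10 FN=20
  labels <- c(rep(1, 40), rep(1, 20), rep(0, 30), rep(0, 10))
  probs <- c(rep(0.9, 40), rep(0.1, 20), rep(0.1, 30), rep(0.9, 10))
  rep <- compute_metrics(labels, probs)
  expect_equal(unlist(rep[c("TP", "TN", "FP", "FN")]),
               c(TP = 40, TN = 30, FP = 10, FN = 20))
  expect_equal(rep$ACC, 0.70)
  expect_equal(rep$SEN, 0.6667, tolerance = 1e-4)
  expect_equal(rep$SPE, 0.75)
  expect_equal(rep$PRE, 0.80)
  expect_equal(rep$F1, 0.7273, tolerance = 1e-4)
  expect_equal(rep$MCC, 1000 / sqrt(6e6)) # = 0.4082 at printed precision

  # degenerate single-class input flags the undefined ratios
  deg <- compute_metrics(c(1, 1), c(0.9, 0.2))
  expect_true(grepl("SPE", deg$undefined) && grepl("AUROC", deg$undefined))
  expect_equal(deg$SPE, 0)
})

test_that("rank-based AUROC equals pairwise comparison and pROC on tied scores", {
  skip_if_not_installed("pROC")
  for (s in 1:10) {
    withr::with_seed(s, {
      n <- sample(20:200, 1)
      labels <- rbinom(n, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      probs <- round(runif(n), 1) # heavy ties
    })
    got <- compute_metrics(labels, probs)$AUROC
    pos <- probs[labels == 1]; neg <- probs[labels == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(got, mean(cmp))
    expect_equal(got,
                 as.numeric(pROC::auc(labels, probs, direction = "<",
                                      quiet = TRUE)))
  }
})

test_that("metric identities hold across random reports", {
  for (s in 1:20) {
    withr::with_seed(s, {
      labels <- rbinom(50, 1, 0.5)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      probs <- runif(50)
    })
    rep <- compute_metrics(labels, probs)
    P <- sum(labels == 1); N <- sum(labels == 0)
    expect_equal(rep$ACC, (rep$SEN * P + rep$SPE * N) / (P + N))
    # swapping class labels together with predictions preserves MCC
    swapped <- compute_metrics(1 - labels, 1 - probs)
    expect_equal(swapped$MCC, rep$MCC, tolerance = 1e-12)
  }
})

test_that("training is seeded-deterministic and learns a planted motif", {
  corpus <- tiny_corpus(100, 100, seed = 4, mutation_rate = 0,
                        motif_offset_jitter = 0)
  vocab <- corpus_vocabulary(corpus, kmer = 2)
  prep <- lncpair:::prepare_fold_data(
    corpus, length_policy("start", X = 15), length_policy("max_pad"),
    vocab, corpus$pairs)
  tok <- encode_pairs(prep$lnc, prep$partner, corpus$pairs, vocab, prep$pad)
  make_model <- function() do.call(
    lncpair_model, c(list(vocab_size = vocab$size, seed = 2), tiny_model_args))
  cfg <- train_config(max_epochs = 3, batch_size = 32, seed = 9)

  fit1 <- train_model(make_model(), tok, cfg)
  fit2 <- train_model(make_model(), tok, cfg)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$log, fit2$log)

  # loss decreases across the first epochs on separable data
  expect_true(all(diff(fit1$log$train_loss) < 0))
  # the converged toy model scores most training positives above 0.5
  pr <- predict(fit1, tok)
  expect_gt(mean(pr[tok$labels == 1] > 0.5), 0.9)

  # degenerate inputs
  fit0 <- train_model(make_model(), tok, train_config(max_epochs = 0))
  expect_identical(fit0$model$params, make_model()$params)
  single <- lncpair:::subset_tokens(tok, which(tok$labels == 1))
  expect_error(train_model(make_model(), single, cfg), "both classes")
})

test_that("cross-validation folds cover the corpus and average coherently", {
  corpus <- tiny_corpus(40, 40, seed = 6)
  cv <- cross_validate(corpus, length_policy("start", X = 10), kmer = 2,
                       model_args = tiny_model_args,
                       train = train_config(max_epochs = 2, batch_size = 32),
                       n_folds = 4, seed = 3)
  expect_equal(nrow(cv$folds), 4)
  expect_equal(sum(cv$folds$TP + cv$folds$TN + cv$folds$FP + cv$folds$FN),
               nrow(corpus$pairs)) # test folds partition the corpus
  expect_equal(cv$mean$ACC, mean(cv$folds$ACC))
  expect_equal(glance(cv), cv$mean)
})

test_that("grid search ranks candidates by the validation metric", {
  corpus <- tiny_corpus(40, 40, seed = 8)
  gs1 <- grid_search(corpus, list(kmer = 2), length_policy("start", X = 10),
                     max_epochs = 2, seed = 5)
  expect_equal(nrow(gs1$leaderboard), 1)
  expect_equal(gs1$best$kmer, 2)

  gs <- grid_search(corpus, list(kmer = 2, n_hidden = c(4, 8)),
                    length_policy("start", X = 10), max_epochs = 2, seed = 5)
  expect_equal(nrow(gs$leaderboard), 2)
  expect_true(!is.unsorted(rev(gs$leaderboard$ACC)))
  expect_equal(gs$best$ACC, max(gs$leaderboard$ACC))
})
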
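#' Construct the recurrent pair classifier
#'
#' Builds the full parameter set of the lightweight sequence-pair classifier:
#' a learned k-mer embedding table (rows drawn from a standard normal, PAD
#' row zero), a single-layer LSTM whose hidden-to-hidden matrices are
#' regularized by DropConnect, max/mean/last pooling over the hidden states
#' (a `3 * n_hidden` feature vector), two batch-normalization layers,
#' standard dropout, a dense sigmoid layer down to `n_dense` features and a
#' dense softmax head over two classes. All dropout rates default to the
#' optimal grid-search values for the lncRNA--miRNA task.
#'
#' @param vocab_size Number of rows of the embedding table (vocabulary size
#'   including PAD/UNK).
#' @param n_embedding Embedding dimension (default 120).
#' @param n_hidden LSTM hidden size H (default 120; the pooled vector is 3H).
#' @param n_dense Width of the compact dense representation (default 50).
#' @param n_classes Output classes (2: interactive / non-interactive).
#' @param p_embed_vector Probability an entire token vector is dropped
#'   during training (default 0.004).
#' @param p_embed_weight Probability an individual embedding entry is
#'   dropped (default 0.005).
#' @param p_dropconnect Probability each hidden-to-hidden weight is zeroed
#'   for an entire forward/backward pass (default 0.004).
#' @param p_dropout Standard dropout rate on the dense head (default 0.1).
#' @param bn_momentum,bn_eps Batch-normalization running-statistics momentum
#'   and numerical-stability constant.
#' @param use_bias Include LSTM gate biases (default `TRUE`; the forget-gate
#'   bias is initialized to 1). `FALSE` gives the literal bias-free gate
#'   equations.
#' @param seed Integer seed for all weight initialization.
#' @return An `lncpair_model` object (lists `params`, `state`, `config`).
#' @export
#' @examples
#' m <- lncpair_model(vocab_size = 6, n_embedding = 4, n_hidden = 3, seed = 1)
#' count_parameters(m)
lncpair_model <- function(vocab_size, n_embedding = 120, n_hidden = 120,
                          n_dense = 50, n_classes = 2,
                          p_embed_vector = 0.004, p_embed_weight = 0.005,
                          p_dropconnect = 0.004, p_dropout = 0.1,
                          bn_momentum = 0.1, bn_eps = 1e-5,
                          use_bias = TRUE, seed = 1) {
  V <- as.integer(vocab_size); d <- as.integer(n_embedding)
  H <- as.integer(n_hidden); D <- as.integer(n_dense); C <- as.integer(n_classes)
  stopifnot(V >= 2, d >= 1, H >= 1, D >= 1, C >= 2)
  params <- withr::with_seed(seed, {
    unif <- function(nr, nc) {
      s <- 1 / sqrt(nr)
      matrix(stats::runif(nr * nc, -s, s), nr, nc)
    }
    E <- matrix(stats::rnorm(V * d), V, d)
    E[1, ] <- 0 # PAD row
    b <- numeric(4 * H)
    if (use_bias) b[(H + 1):(2 * H)] <- 1 # forget-gate bias
    list(
      E = E,
      Wx = unif(d, 4 * H), Uh = unif(H, 4 * H), b = b,
      gamma1 = rep(1, 3 * H), beta1 = rep(0, 3 * H),
      W1 = unif(3 * H, D), b1 = numeric(D),
      gamma2 = rep(1, D), beta2 = rep(0, D),
      W2 = unif(D, C), b2 = numeric(C)
    )
  })
  state <- list(bn1_mean = numeric(3 * H), bn1_var = rep(1, 3 * H),
                bn2_mean = numeric(D), bn2_var = rep(1, D))
  structure(
    list(params = params, state = state,
         config = list(vocab_size = V, n_embedding = d, n_hidden = H,
                       n_dense = D, n_classes = C,
                       p_embed_vector = p_embed_vector,
                       p_embed_weight = p_embed_weight,
                       p_dropconnect = p_dropconnect, p_dropout = p_dropout,
                       bn_momentum = bn_momentum, bn_eps = bn_eps,
                       use_bias = use_bias, seed = as.integer(seed))),
    class = "lncpair_model"
  )
}

#' @export
print.lncpair_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<lncpair_model> vocab %d, embed %d, hidden %d (pooled %d), dense %d -> %d; %d trainable parameters\n",
    cfg$vocab_size, cfg$n_embedding, cfg$n_hidden, 3 * cfg$n_hidden,
    cfg$n_dense, cfg$n_classes, count_parameters(x)))
  invisible(x)
}

#' Count trainable scalars of a model
#'
#' Embedding table, the eight LSTM gate matrices plus biases, both
#' batch-norm scale/shift vectors and both dense layers; running statistics
#' are not trainable and are excluded.
#'
#' @param model An [lncpair_model()] or a fitted model.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "lncpair_fit")) model <- model$model
  p <- model$params
  if (!model$config$use_bias) p$b <- NULL
  sum(vapply(p, length, integer(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Inverted-dropout mask: entries are 0 with probability p, else 1/(1-p),
# so the expectation over masks is the identity and eval mode needs no
# rescaling. (The classical alternative - scaling activations by (1-p) at
# test time - is available at the dropout layer via scale_at_test.)
dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  if (p >= 1) return(matrix(0, nr, nc))
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

#' Embedding lookup with dual dropout
#'
#' Maps 0-based token ids to their embedding rows. In training mode whole
#' token vectors are zeroed with probability `p_embed_vector` and individual
#' entries with probability `p_embed_weight` (inverted dropout); eval mode
#' is a deterministic lookup.
#'
#' @param model An [lncpair_model()].
#' @param ids Integer matrix (instances x tokens) of 0-based token ids.
#' @param training Apply dropout?
#' @return Array of dim `(n_instances, n_tokens, n_embedding)`.
#' @export
embed_tokens <- function(model, ids, training = FALSE) {
  cfg <- model$config
  if (any(ids < 0L) || any(ids >= cfg$vocab_size)) {
    stop("token id out of range for vocabulary of size ", cfg$vocab_size,
         call. = FALSE)
  }
  B <- nrow(ids); Tn <- ncol(ids); d <- cfg$n_embedding
  X <- model$params$E[as.vector(ids) + 1L, , drop = FALSE] # (B*Tn) x d
  if (training) {
    vec_mask <- dropout_mask(B * Tn, 1, cfg$p_embed_vector)
    if (!is.null(vec_mask)) X <- X * as.vector(vec_mask)
    w_mask <- dropout_mask(B * Tn, d, cfg$p_embed_weight)
    if (!is.null(w_mask)) X <- X * w_mask
  }
  array(X, dim = c(B, Tn, d))
}

#' Single-layer LSTM forward pass
#'
#' Iterates the gate equations
#' \deqn{i_t = \sigma(W^i x_t + U^i h_{t-1} + b^i)}
#' (and likewise for the forget and output gates and the tanh candidate)
#' with the standard cell update \eqn{c_t = f_t \odot c_{t-1} + i_t \odot
#' \tilde{c}_t} and \eqn{h_t = o_t \odot \tanh(c_t)}, starting from
#' \eqn{h_0 = c_0 = 0}. In training mode a single DropConnect mask zeroes
#' entries of the hidden-to-hidden matrices for the entire pass.
#'
#' @param model An [lncpair_model()].
#' @param x Array `(B, T, d)` of input vectors (see [embed_tokens()]), or a
#'   matrix `(T, d)` for a single instance.
#' @param training Sample a DropConnect mask?
#' @return Array `(B, T, H)` of hidden states (matrix `(T, H)` if the input
#'   was a matrix).
#' @export
lstm_forward <- function(model, x, training = FALSE) {
  single <- is.matrix(x)
  if (single) x <- array(x, dim = c(1, nrow(x), ncol(x)))
  cache <- lstm_forward_cache(model$params, model$config, x, training)
  H <- model$config$n_hidden
  B <- dim(x)[1]; Tn <- dim(x)[2]
  hs <- array(0, dim = c(B, Tn, H))
  for (t in seq_len(Tn)) hs[, t, ] <- cache$h[[t]]
  if (single) matrix(hs[1, , ], Tn, H) else hs
}

# Internal forward with full cache for backprop.
lstm_forward_cache <- function(params, cfg, x, training) {
  B <- dim(x)[1]; Tn <- dim(x)[2]; H <- cfg$n_hidden
  if (Tn < 1) stop("empty input sequence", call. = FALSE)
  if (dim(x)[3] != nrow(params$Wx)) stop("dimension mismatch: input vs W", call. = FALSE)
  Umask <- if (training && cfg$p_dropconnect > 0) {
    dropout_mask(H, 4 * H, cfg$p_dropconnect)
  } else NULL
  U <- if (is.null(Umask)) params$Uh else params$Uh * Umask
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  ii <- seq_len(H); fi <- H + ii; oi <- 2 * H + ii; gi <- 3 * H + ii
  st <- list(i = vector("list", Tn), f = vector("list", Tn),
             o = vector("list", Tn), g = vector("list", Tn),
             c = vector("list", Tn), tc = vector("list", Tn),
             h = vector("list", Tn))
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], B)
    G <- xt %*% params$Wx + h %*% U
    G <- sweep(G, 2, params$b, "+")
    i_t <- sigmoid(G[, ii, drop = FALSE])
    f_t <- sigmoid(G[, fi, drop = FALSE])
    o_t <- sigmoid(G[, oi, drop = FALSE])
    g_t <- tanh(G[, gi, drop = FALSE])
    c <- f_t * c + i_t * g_t
    tc <- tanh(c)
    h <- o_t * tc
    st$i[[t]] <- i_t; st$f[[t]] <- f_t; st$o[[t]] <- o_t; st$g[[t]] <- g_t
    st$c[[t]] <- c; st$tc[[t]] <- tc; st$h[[t]] <- h
  }
  st$Umask <- Umask; st$U <- U; st$x <- x
  st
}

#' Triple pooling of LSTM hidden states
#'
#' Concatenates the elementwise maximum over time, the elementwise mean over
#' time, and the last hidden state, in that order; the output dimension is
#' exactly `3 * H`.
#'
#' @param h Array `(B, T, H)` of hidden states, or a matrix `(T, H)` for a
#'   single instance.
#' @return Matrix `(B, 3H)` (or a length-`3H` vector for matrix input) with
#'   an `"argmax"` attribute used by backpropagation.
#' @export
#' @examples
#' pool_states(rbind(c(1, 2), c(3, 0), c(2, 2)))
pool_states <- function(h) {
  single <- is.matrix(h)
  if (single) h <- array(h, dim = c(1, nrow(h), ncol(h)))
  B <- dim(h)[1]; Tn <- dim(h)[2]; H <- dim(h)[3]
  if (Tn < 1) stop("at least one hidden state required", call. = FALSE)
  mx <- matrix(-Inf, B, H); amx <- matrix(1L, B, H); sm <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    ht <- matrix(h[, t, ], B)
    upd <- ht > mx
    amx[upd] <- t
    mx[upd] <- ht[upd]
    sm <- sm + ht
  }
  out <- cbind(mx, sm / Tn, matrix(h[, Tn, ], B))
  attr(out, "argmax") <- amx
  if (single) {
    v <- out[1, ]
    attr(v, "argmax") <- amx[1, ]
    v
  } else out
}

#' Batch normalization
#'
#' Training mode normalizes each feature by the batch mean and (biased)
#' variance, then scales and shifts by the learned `gamma`/`beta`, and
#' updates running statistics by an exponential moving average; eval mode
#' normalizes by the running statistics. Training requires a batch of at
#' least 2.
#'
#' @param x Feature matrix (batch x features).
#' @param gamma,beta Learned scale and shift vectors.
#' @param running_mean,running_var Inference-time statistics.
#' @param training Use batch statistics (and update running ones)?
#' @param momentum EMA momentum for the running statistics.
#' @param eps Numerical-stability constant.
#' @return List with `y` (normalized output), updated `running_mean` /
#'   `running_var`, and a `cache` for backpropagation.
#' @export
batch_norm <- function(x, gamma, beta, running_mean, running_var,
                       training = FALSE, momentum = 0.1, eps = 1e-5) {
  x <- as.matrix(x)
  if (training) {
    if (nrow(x) < 2) stop("batch normalization in training mode requires batch size >= 2",
                          call. = FALSE)
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    running_var <- (1 - momentum) * running_var + momentum * v
  } else {
    mu <- running_mean
    v <- running_var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, ivar, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, running_mean = running_mean, running_var = running_var,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, training = training))
}

batch_norm_backward <- function(dy, cache) {
  xhat <- cache$xhat; ivar <- cache$ivar
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, cache$gamma, "*")
  if (cache$training) {
    mean_dxhat <- colMeans(dxhat)
    mean_dxhat_xhat <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, mean_dxhat) - sweep(xhat, 2, mean_dxhat_xhat, "*")
    dx <- sweep(dx, 2, ivar, "*")
  } else {
    dx <- sweep(dxhat, 2, ivar, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Full forward pass; returns probabilities plus the cache needed by
# model_backward and the updated batch-norm running state.
model_forward <- function(model, ids, training = FALSE,
                          scale_at_test = FALSE) {
  cfg <- model$config; p <- model$params
  B <- nrow(ids)
  # --- embedding (with dual dropout) ---
  d <- cfg$n_embedding
  if (any(ids < 0L) || any(ids >= cfg$vocab_size)) {
    stop("token id out of range", call. = FALSE)
  }
  X <- p$E[as.vector(ids) + 1L, , drop = FALSE]
  emb_mask <- NULL
  if (training) {
    vec_mask <- dropout_mask(length(ids), 1, cfg$p_embed_vector)
    w_mask <- dropout_mask(length(ids), d, cfg$p_embed_weight)
    if (!is.null(vec_mask) || !is.null(w_mask)) {
      emb_mask <- (if (is.null(vec_mask)) 1 else as.vector(vec_mask)) *
        (if (is.null(w_mask)) 1 else w_mask)
      X <- X * emb_mask
    }
  }
  Xa <- array(X, dim = c(B, ncol(ids), d))
  # --- LSTM ---
  lstm <- lstm_forward_cache(p, cfg, Xa, training)
  Tn <- ncol(ids)
  hs <- array(0, dim = c(B, Tn, cfg$n_hidden))
  for (t in seq_len(Tn)) hs[, t, ] <- lstm$h[[t]]
  # --- pooling ---
  P <- pool_states(hs)
  argmax <- attr(P, "argmax")
  attr(P, "argmax") <- NULL
  # --- BN -> dropout -> dense(sigmoid) -> BN -> dropout -> dense -> softmax
  bn1 <- batch_norm(P, p$gamma1, p$beta1, model$state$bn1_mean,
                    model$state$bn1_var, training, cfg$bn_momentum, cfg$bn_eps)
  h1 <- bn1$y
  m1 <- if (training) dropout_mask(nrow(h1), ncol(h1), cfg$p_dropout) else NULL
  if (!is.null(m1)) h1 <- h1 * m1
  if (!training && scale_at_test) h1 <- h1 * (1 - cfg$p_dropout)
  Z1 <- sweep(h1 %*% p$W1, 2, p$b1, "+")
  A1 <- sigmoid(Z1)
  bn2 <- batch_norm(A1, p$gamma2, p$beta2, model$state$bn2_mean,
                    model$state$bn2_var, training, cfg$bn_momentum, cfg$bn_eps)
  h2 <- bn2$y
  m2 <- if (training) dropout_mask(nrow(h2), ncol(h2), cfg$p_dropout) else NULL
  if (!is.null(m2)) h2 <- h2 * m2
  if (!training && scale_at_test) h2 <- h2 * (1 - cfg$p_dropout)
  Z2 <- sweep(h2 %*% p$W2, 2, p$b2, "+")
  probs <- softmax_rows(Z2)
  list(
    probs = probs,
    state = list(bn1_mean = bn1$running_mean, bn1_var = bn1$running_var,
                 bn2_mean = bn2$running_mean, bn2_var = bn2$running_var),
    cache = list(ids = ids, emb_mask = emb_mask, X = Xa, lstm = lstm, hs = hs,
                 P = P, argmax = argmax, bn1 = bn1$cache, m1 = m1, h1 = h1,
                 A1 = A1, bn2 = bn2$cache, m2 = m2, h2 = h2, B = B, Tn = Tn)
  )
}

# Backpropagate the mean cross-entropy loss through the full network.
# Returns gradients with the same names/shapes as model$params.
model_backward <- function(model, fw, labels) {
  cfg <- model$config; p <- model$params; ca <- fw$cache
  B <- ca$B; Tn <- ca$Tn; H <- cfg$n_hidden
  onehot <- matrix(0, B, cfg$n_classes)
  onehot[cbind(seq_len(B), labels + 1L)] <- 1
  dZ2 <- (fw$probs - onehot) / B
  dW2 <- crossprod(ca$h2, dZ2)
  db2 <- colSums(dZ2)
  dh2 <- dZ2 %*% t(p$W2)
  if (!is.null(ca$m2)) dh2 <- dh2 * ca$m2
  bn2b <- batch_norm_backward(dh2, ca$bn2)
  dZ1 <- bn2b$dx * ca$A1 * (1 - ca$A1)
  dW1 <- crossprod(ca$h1, dZ1)
  db1 <- colSums(dZ1)
  dh1 <- dZ1 %*% t(p$W1)
  if (!is.null(ca$m1)) dh1 <- dh1 * ca$m1
  bn1b <- batch_norm_backward(dh1, ca$bn1)
  dP <- bn1b$dx
  # --- unpool: [max | mean | last] ---
  dmax <- dP[, 1:H, drop = FALSE]
  dmean <- dP[, (H + 1):(2 * H), drop = FALSE]
  dlast <- dP[, (2 * H + 1):(3 * H), drop = FALSE]
  dH_t <- vector("list", Tn)
  for (t in seq_len(Tn)) dH_t[[t]] <- dmean / Tn
  dH_t[[Tn]] <- dH_t[[Tn]] + dlast
  amx <- ca$argmax
  for (t in seq_len(Tn)) {
    sel <- amx == t
    if (any(sel)) dH_t[[t]][sel] <- dH_t[[t]][sel] + dmax[sel]
  }
  # --- BPTT ---
  lst <- ca$lstm
  U <- lst$U
  ii <- seq_len(H); fi <- H + ii; oi <- 2 * H + ii; gi <- 3 * H + ii
  dWx <- matrix(0, nrow(p$Wx), ncol(p$Wx))
  dU <- matrix(0, H, 4 * H)
  db <- numeric(4 * H)
  dX <- array(0, dim = dim(ca$X))
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  for (t in Tn:1) {
    dh <- dH_t[[t]] + dh_next
    i_t <- lst$i[[t]]; f_t <- lst$f[[t]]; o_t <- lst$o[[t]]; g_t <- lst$g[[t]]
    tc <- lst$tc[[t]]
    c_prev <- if (t > 1) lst$c[[t - 1]] else matrix(0, B, H)
    h_prev <- if (t > 1) lst$h[[t - 1]] else matrix(0, B, H)
    do_ <- dh * tc
    dc <- dc_next + dh * o_t * (1 - tc^2)
    di <- dc * g_t
    dg <- dc * i_t
    df <- dc * c_prev
    dc_next <- dc * f_t
    dG <- cbind(di * i_t * (1 - i_t),
                df * f_t * (1 - f_t),
                do_ * o_t * (1 - o_t),
                dg * (1 - g_t^2))
    xt <- matrix(ca$X[, t, ], B)
    dWx <- dWx + crossprod(xt, dG)
    dU <- dU + crossprod(h_prev, dG)
    db <- db + colSums(dG)
    dX[, t, ] <- dG %*% t(p$Wx)
    dh_next <- dG %*% t(U)
  }
  if (!is.null(lst$Umask)) dU <- dU * lst$Umask
  if (!cfg$use_bias) db <- db * 0
  # --- embedding gradient (scatter-add by token id) ---
  dXflat <- matrix(dX, B * Tn, cfg$n_embedding)
  if (!is.null(ca$emb_mask)) dXflat <- dXflat * ca$emb_mask
  idvec <- as.vector(ca$ids) + 1L
  dE <- matrix(0, cfg$vocab_size, cfg$n_embedding)
  agg <- rowsum(dXflat, group = idvec)
  dE[as.integer(rownames(agg)), ] <- agg
  list(E = dE, Wx = dWx, Uh = dU, b = db,
       gamma1 = bn1b$dgamma, beta1 = bn1b$dbeta,
       W1 = dW1, b1 = db1,
       gamma2 = bn2b$dgamma, beta2 = bn2b$dbeta,
       W2 = dW2, b2 = db2)
}

#' Loss, probabilities and gradients for a batch
#'
#' Runs the full forward pass (embedding, LSTM, pooling, batch norm, dense
#' head, softmax) and backpropagates the mean categorical cross-entropy.
#' All stochastic layers draw their masks from the current RNG stream in
#' training mode.
#'
#' @param model An [lncpair_model()].
#' @param ids 0-based token id matrix (instances x tokens).
#' @param labels Integer 0/1 labels.
#' @param training Training mode (dropout active, batch-norm batch
#'   statistics)?
#' @return List with `loss`, `probs` (rows sum to 1), `grads` (same shapes
#'   as the parameters) and the updated batch-norm `state`.
#' @export
model_loss_grads <- function(model, ids, labels, training = TRUE) {
  fw <- model_forward(model, ids, training = training)
  eps <- 1e-12
  loss <- -mean(log(pmax(fw$probs[cbind(seq_along(labels), labels + 1L)], eps)))
  grads <- model_backward(model, fw, labels)
  list(loss = loss, probs = fw$probs, grads = grads, state = fw$state)
}

#' Predict class probabilities with a model
#'
#' Eval-mode forward pass (deterministic: no dropout, batch norm uses
#' running statistics), in chunks.
#'
#' @param model An [lncpair_model()] or [train_model()] fit.
#' @param ids Token id matrix, or a `tokenized_pairs` object.
#' @param batch_size Chunk size.
#' @return Matrix (instances x 2) of class probabilities; column 2 is the
#'   interactive-class probability.
#' @export
predict_proba <- function(model, ids, batch_size = 512) {
  if (inherits(model, "lncpair_fit")) model <- model$model
  if (inherits(ids, "tokenized_pairs")) ids <- ids$ids
  n <- nrow(ids)
  out <- matrix(NA_real_, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out[idx, ] <- model_forward(model, ids[idx, , drop = FALSE],
                                training = FALSE)$probs
  }
  out
}
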
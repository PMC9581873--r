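#' Training configuration
#'
#' Defaults are the optimal grid-search values for the lncRNA--miRNA task:
#' learning rate 0.01, decoupled weight decay 0.02, batch size 64. The
#' learning rate is multiplied by `lr_decay` after every epoch, and training
#' early-stops when the validation loss has not improved for `patience`
#' epochs. For the lncRNA--protein task the reported optima are
#' `learning_rate = 0.05`, `weight_decay = 0.01`.
#'
#' @param learning_rate Initial learning rate (> 0).
#' @param weight_decay Decoupled weight-decay coefficient lambda (>= 0).
#' @param batch_size Mini-batch size (>= 2; batch norm needs at least 2).
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation loss.
#' @param lr_decay Per-epoch multiplicative learning-rate decay.
#' @param seed Integer seed driving shuffling and all dropout masks.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, weight_decay = 0.02,
                         batch_size = 64, max_epochs = 100, patience = 5,
                         lr_decay = 0.95, seed = 1) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 2,
            max_epochs >= 0, lr_decay > 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr_decay = lr_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize AdamW optimizer state
#'
#' @param params Named list of parameter arrays.
#' @return Optimizer state (step counter and first/second moments).
#' @export
adamw_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0) # zeros with p's exact shape
  list(t = 0L, m = zeros, v = zeros)
}

#' One decoupled-weight-decay Adam (AdamW) step
#'
#' The Adam moment estimates are computed on the raw gradients - the weight
#' decay is *not* folded into the gradient (that would be L2 regularization,
#' which Adam's adaptive scaling distorts). The update is
#' \deqn{w \leftarrow w - \mathrm{lr}\,\hat m / (\sqrt{\hat v} + \epsilon)
#'   - \mathrm{lr}\,\lambda\, w.}
#' With `weight_decay = 0` this is plain Adam.
#'
#' @param params,grads Named lists of identically shaped arrays.
#' @param state Optimizer state from [adamw_init()].
#' @param lr Learning rate for this step.
#' @param weight_decay Decoupled decay coefficient lambda.
#' @param beta1,beta2,eps Adam moment decay rates and stability constant.
#' @return List with updated `params` and `state`.
#' @export
adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bad <- names(grads)[!vapply(grads, function(g) all(is.finite(g)), logical(1))]
  if (length(bad) > 0) stop("non-finite gradient in tensor '", bad[1], "'", call. = FALSE)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps) -
      lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' Train the pair classifier
#'
#' Minimizes the categorical cross-entropy over shuffled mini-batches with
#' AdamW (decoupled weight decay) and per-epoch learning-rate decay. When a
#' validation set is supplied, training early-stops on validation loss and
#' the returned fit carries the parameters of the best validation epoch.
#' Fully reproducible for a fixed `config$seed`. Trailing batches of size 1
#' are skipped (batch normalization needs at least 2 instances).
#'
#' @param model An [lncpair_model()].
#' @param data Training set (`tokenized_pairs`), containing both classes.
#' @param config A [train_config()].
#' @param val Optional validation set (`tokenized_pairs`).
#' @return An `lncpair_fit`: the trained `model`, a per-epoch `log` tibble
#'   (`epoch`, `lr`, `train_loss`, `val_loss`), `best_epoch` and the
#'   resolved `config`.
#' @export
train_model <- function(model, data, config = train_config(), val = NULL) {
  labels <- data$labels
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(data$ids)
  fit <- structure(
    list(model = model, log = tibble::tibble(
      epoch = integer(), lr = double(), train_loss = double(),
      val_loss = double()),
      best_epoch = NA_integer_, config = config),
    class = "lncpair_fit")
  if (config$max_epochs == 0) return(fit)
  withr::with_seed(config$seed, {
    opt <- adamw_init(model$params)
    lr <- config$learning_rate
    best_val <- Inf; best_params <- model$params; best_state <- model$state
    best_epoch <- NA_integer_; stale <- 0L
    log_rows <- vector("list", config$max_epochs)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = config$batch_size)
      total_loss <- 0; total_n <- 0L
      for (s in batch_starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        if (length(idx) < 2) next
        lg <- model_loss_grads(model, data$ids[idx, , drop = FALSE],
                               labels[idx], training = TRUE)
        model$state <- lg$state
        step <- adamw_step(model$params, lg$grads, opt, lr,
                           config$weight_decay)
        model$params <- step$params
        opt <- step$state
        total_loss <- total_loss + lg$loss * length(idx)
        total_n <- total_n + length(idx)
      }
      train_loss <- total_loss / total_n
      val_loss <- NA_real_
      if (!is.null(val)) {
        vp <- predict_proba(model, val)
        val_loss <- -mean(log(pmax(
          vp[cbind(seq_along(val$labels), val$labels + 1L)], 1e-12)))
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss; best_params <- model$params
          best_state <- model$state; best_epoch <- epoch; stale <- 0L
        } else {
          stale <- stale + 1L
        }
      }
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, train_loss = train_loss, val_loss = val_loss)
      lr <- lr * config$lr_decay
      if (!is.null(val) && stale >= config$patience) break
    }
    if (!is.null(val) && is.finite(best_val)) {
      model$params <- best_params
      model$state <- best_state
    } else {
      best_epoch <- epoch
    }
    fit$model <- model
    fit$log <- dplyr::bind_rows(log_rows)
    fit$best_epoch <- best_epoch
    fit
  })
}

#' @export
print.lncpair_fit <- function(x, ...) {
  cat(sprintf("<lncpair_fit> %d epoch(s), best epoch %s; %d parameters\n",
              nrow(x$log), x$best_epoch, count_parameters(x)))
  invisible(x)
}

#' @export
predict.lncpair_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pr <- predict_proba(object, newdata)
  if (type == "prob") pr[, 2] else as.integer(pr[, 2] >= 0.5)
}

#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.lncpair_fit <- function(x, ...) x$log

#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.lncpair_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    best_epoch = x$best_epoch,
    best_val_loss = if (all(is.na(x$log$val_loss))) NA_real_ else
      min(x$log$val_loss, na.rm = TRUE),
    final_train_loss = if (nrow(x$log)) x$log$train_loss[nrow(x$log)] else NA_real_,
    n_parameters = count_parameters(x)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.lncpair_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, c("train_loss", "val_loss"),
                            names_to = "set", values_to = "loss")
  df <- df[is.finite(df$loss), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a fitted model
#'
#' The checkpoint is a single RDS archive holding the parameter arrays,
#' batch-norm running statistics, model and training configuration, and any
#' attached vocabulary/length-policy metadata.
#'
#' @param fit An `lncpair_fit` (or `lncpair_model`).
#' @param path Checkpoint path.
#' @param meta Optional named list stored alongside (e.g. vocabulary and
#'   length policies).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored object.
#' @export
save_model <- function(fit, path, meta = NULL) {
  saveRDS(list(format = "lncpair-checkpoint-1", fit = fit, meta = meta), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "lncpair-checkpoint-1")) {
    stop("not an lncpair checkpoint: ", path, call. = FALSE)
  }
  x
}
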
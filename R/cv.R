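derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Fixed-length + tokenized view of a corpus under a pair of policies, using
# length statistics from the training split only.
prepare_fold_data <- function(corpus, lnc_policy, partner_policy, vocab,
                              train_pairs) {
  lnc_stats <- corpus_length_stats(
    corpus$lnc[corpus$lnc$id %in% train_pairs$a_id, ])
  partner_stats <- corpus_length_stats(
    corpus$partner[corpus$partner$id %in% train_pairs$b_id, ])
  lnc_fixed <- apply_policy(corpus$lnc, lnc_policy, lnc_stats)
  partner_fixed <- apply_policy(corpus$partner, partner_policy, partner_stats)
  list(lnc = lnc_fixed, partner = partner_fixed, vocab = vocab,
       pad = lnc_policy$pad)
}

#' Build the tokenizer for a corpus
#'
#' One k-mer vocabulary per segment alphabet; for mixed-alphabet tasks the
#' partner vocabulary is offset into a single index space.
#'
#' @param corpus A [paired_corpus()].
#' @param kmer K-mer order (5 is the reported optimum for RNA--RNA, 1 for
#'   RNA--protein).
#' @param stride Window stride (default 1, overlapping).
#' @return A [pair_vocabulary()].
#' @export
corpus_vocabulary <- function(corpus, kmer = 5, stride = 1) {
  lnc_v <- kmer_vocabulary(corpus$lnc$alphabet[1], kmer, stride)
  partner_alpha <- corpus$partner$alphabet[1]
  if (identical(partner_alpha, lnc_v$alphabet)) {
    pair_vocabulary(lnc_v)
  } else {
    pair_vocabulary(lnc_v, kmer_vocabulary(partner_alpha, kmer, stride))
  }
}

#' Stratified k-fold cross-validation of the pair classifier
#'
#' Splits the corpus pairs into `n_folds` label-stratified folds; for each
#' fold, corpus length statistics are computed on the training split,
#' sequences are made fixed-length under the two policies, tokenized, and a
#' fresh model is trained (with `val_fraction` of the training split as the
#' early-stopping validation set) and evaluated on the held-out fold.
#'
#' @param corpus A [paired_corpus()].
#' @param lnc_policy [length_policy()] for the lncRNA side.
#' @param partner_policy [length_policy()] for the partner side (default:
#'   pad to the training-split maximum, the convention for short miRNAs).
#' @param kmer,stride Tokenizer settings.
#' @param model_args Named list of overrides passed to [lncpair_model()].
#' @param train A [train_config()].
#' @param n_folds Number of folds (default 5).
#' @param val_fraction Validation fraction within each training split
#'   (default 0.1).
#' @param seed Integer seed (folds, initialization and training all derive
#'   from it).
#' @param keep_fits Keep the per-fold fitted models?
#' @return A `cv_result`: tibble `folds` (per-fold metrics), tibble `mean`
#'   (unweighted fold means), and optionally `fits`.
#' @export
cross_validate <- function(corpus, lnc_policy,
                           partner_policy = length_policy("max_pad"),
                           kmer = 5, stride = 1, model_args = list(),
                           train = train_config(), n_folds = 5,
                           val_fraction = 0.1, seed = 1, keep_fits = FALSE) {
  folds <- split_folds(corpus$pairs, n_folds, val_fraction, seed)
  vocab <- corpus_vocabulary(corpus, kmer, stride)
  fold_rows <- vector("list", n_folds)
  fits <- if (keep_fits) vector("list", n_folds) else NULL
  for (f in seq_len(n_folds)) {
    val_col <- folds[[paste0("val_f", f)]]
    test_pairs <- folds[folds$fold == f, ]
    val_pairs <- folds[folds$fold != f & val_col, ]
    train_pairs <- folds[folds$fold != f & !val_col, ]
    prep <- prepare_fold_data(corpus, lnc_policy, partner_policy, vocab,
                              dplyr::bind_rows(train_pairs, val_pairs))
    enc <- function(p) encode_pairs(prep$lnc, prep$partner, p, vocab, prep$pad)
    train_tok <- enc(train_pairs)
    val_tok <- if (nrow(val_pairs) > 0) enc(val_pairs) else NULL
    test_tok <- enc(test_pairs)
    model <- do.call(lncpair_model, utils::modifyList(
      list(vocab_size = vocab$size, seed = derive_seed(seed, f)), model_args))
    cfg <- train
    cfg$seed <- derive_seed(seed, 100 + f)
    fit <- train_model(model, train_tok, cfg, val = val_tok)
    rep <- compute_metrics(test_tok$labels, predict_proba(fit, test_tok))
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), rep)
    if (keep_fits) fits[[f]] <- fit
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  mean_tbl <- dplyr::summarise(
    folds_tbl,
    dplyr::across(c("ACC", "SPE", "SEN", "PRE", "F1", "MCC", "AUROC"), mean))
  structure(list(folds = folds_tbl, mean = mean_tbl, fits = fits,
                 n_folds = n_folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds; mean ACC %.4f, MCC %.4f, AUROC %.4f\n",
              x$n_folds, x$mean$ACC, x$mean$MCC, x$mean$AUROC))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cv_result <- function(x, ...) x$folds

#' @exportS3Method generics::glance
glance.cv_result <- function(x, ...) x$mean

#' Sweep sub-sequence settings and residue budgets
#'
#' Runs [cross_validate()] for every combination of region setting
#' (`"start"`, `"end"`, `"start_end"`) and residue budget, reproducing the
#' region-informativeness experiment design (budgets default to 5..50 in
#' steps of 5). For `"start_end"` the budget is used for both `X` and `Y`.
#'
#' @param corpus A [paired_corpus()].
#' @param budgets Integer vector of X/Y values.
#' @param settings Subset of `c("start", "end", "start_end")`.
#' @param ... Passed on to [cross_validate()].
#' @param seed Integer seed shared across cells so settings are compared on
#'   identical folds.
#' @return A `region_sweep` tibble: `setting`, `budget`, and the mean
#'   cross-validated metrics per cell.
#' @export
region_sweep <- function(corpus, budgets = seq(5, 50, by = 5),
                         settings = c("start", "end", "start_end"), ...,
                         seed = 1) {
  settings <- match.arg(settings, several.ok = TRUE)
  grid <- tidyr::expand_grid(setting = settings, budget = as.integer(budgets))
  rows <- purrr::pmap(grid, function(setting, budget) {
    pol <- switch(setting,
      start = length_policy("start", X = budget),
      end = length_policy("end", Y = budget),
      start_end = length_policy("start_end", X = budget, Y = budget))
    cv <- cross_validate(corpus, pol, ..., seed = seed)
    dplyr::bind_cols(tibble::tibble(setting = setting, budget = budget),
                     cv$mean)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("region_sweep", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.region_sweep <- function(object, metric = "ACC", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$budget,
                                       y = .data[[metric]],
                                       colour = .data$setting)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "residues taken from the region (X / Y)",
                  y = paste("mean cross-validated", metric),
                  colour = "region") +
    ggplot2::theme_minimal()
}

#' Grid search over model and training hyperparameters
#'
#' Evaluates every combination of the supplied candidate lists on a single
#' stratified train/validation split and ranks them by the selection metric
#' on the validation set. Ties are broken by smaller trainable-parameter
#' count, then by grid order. Recognized grid axes: `kmer`, `stride`,
#' `n_embedding`, `n_hidden`, `p_embed_vector`, `p_embed_weight`,
#' `p_dropconnect`, `p_dropout`, `learning_rate`, `weight_decay`,
#' `batch_size`.
#'
#' @param corpus A [paired_corpus()].
#' @param grid Named list of candidate vectors (a subset of the axes above).
#' @param lnc_policy,partner_policy Length policies (see
#'   [cross_validate()]).
#' @param metric Selection metric column (default `"ACC"`; `"AUROC"` is the
#'   common alternative).
#' @param val_fraction Validation fraction of the corpus.
#' @param max_epochs,patience Training budget per candidate.
#' @param budget Optional cap on the number of grid cells evaluated (in grid
#'   order).
#' @param seed Integer seed.
#' @return A `grid_search` result: `best` (one-row tibble) and
#'   `leaderboard` (all evaluated cells, ranked).
#' @export
grid_search <- function(corpus, grid, lnc_policy,
                        partner_policy = length_policy("max_pad"),
                        metric = "ACC", val_fraction = 0.1,
                        max_epochs = 10, patience = 3, budget = NULL,
                        seed = 1) {
  stopifnot(length(grid) > 0, all(lengths(grid) > 0))
  cells <- tidyr::expand_grid(!!!grid)
  if (!is.null(budget)) cells <- cells[seq_len(min(budget, nrow(cells))), ]
  pairs <- corpus$pairs
  val_idx <- withr::with_seed(derive_seed(seed, 7), {
    sel <- logical(nrow(pairs))
    for (s in unique(pairs$label)) {
      cand <- which(pairs$label == s)
      n_val <- max(1L, round(val_fraction * length(cand)))
      sel[cand[sample.int(length(cand), n_val)]] <- TRUE
    }
    sel
  })
  train_pairs <- pairs[!val_idx, ]
  val_pairs <- pairs[val_idx, ]
  model_axes <- c("n_embedding", "n_hidden", "p_embed_vector",
                  "p_embed_weight", "p_dropconnect", "p_dropout")
  train_axes <- c("learning_rate", "weight_decay", "batch_size")
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- as.list(cells[i, ])
    kmer <- cell$kmer %||% 5
    stride <- cell$stride %||% 1
    vocab <- corpus_vocabulary(corpus, kmer, stride)
    prep <- prepare_fold_data(corpus, lnc_policy, partner_policy, vocab,
                              train_pairs)
    train_tok <- encode_pairs(prep$lnc, prep$partner, train_pairs, vocab, prep$pad)
    val_tok <- encode_pairs(prep$lnc, prep$partner, val_pairs, vocab, prep$pad)
    model <- do.call(lncpair_model, c(
      list(vocab_size = vocab$size, seed = derive_seed(seed, i)),
      cell[intersect(names(cell), model_axes)]))
    tc <- do.call(train_config, c(
      list(max_epochs = max_epochs, patience = patience,
           seed = derive_seed(seed, 1000 + i)),
      cell[intersect(names(cell), train_axes)]))
    fit <- train_model(model, train_tok, tc, val = val_tok)
    rep <- compute_metrics(val_tok$labels, predict_proba(fit, val_tok))
    rows[[i]] <- dplyr::bind_cols(
      cells[i, ], tibble::tibble(n_parameters = count_parameters(fit)), rep)
  }
  leaderboard <- dplyr::bind_rows(rows)
  leaderboard$.order <- seq_len(nrow(leaderboard))
  leaderboard <- dplyr::arrange(leaderboard,
                                dplyr::desc(.data[[metric]]),
                                .data$n_parameters, .data$.order)
  leaderboard$.order <- NULL
  structure(list(best = leaderboard[1, ], leaderboard = leaderboard,
                 metric = metric),
            class = "grid_search")
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("<grid_search> %d cells ranked by validation %s; best %s = %.4f\n",
              nrow(x$leaderboard), x$metric, x$metric, x$best[[x$metric]]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.grid_search <- function(x, ...) x$leaderboard
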
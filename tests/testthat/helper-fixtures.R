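# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

random_rna <- function(n, len_range = c(30, 60), seed = NULL) {
  draw <- function() {
    syms <- c("A", "C", "G", "U")
    vapply(seq_len(n), function(i) {
      L <- len_range[1] + sample.int(len_range[2] - len_range[1] + 1, 1) - 1
      paste0(sample(syms, L, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

records_tbl <- function(residues, prefix = "s", alphabet = "RNA") {
  tibble::tibble(
    id = sprintf("%s%03d", prefix, seq_along(residues)),
    residues = residues, alphabet = alphabet, length = nchar(residues)
  )
}

# Small fully-synthetic corpus for pipeline tests.
tiny_corpus <- function(n_pos = 30, n_neg = 30, seed = 1, ...) {
  generate_corpus(synthetic_config(n_pos = n_pos, n_neg = n_neg,
                                   lnc_len_range = c(40, 120), seed = seed,
                                   ...))
}

tiny_model_args <- list(n_embedding = 8, n_hidden = 8, n_dense = 6)

# Central-difference gradient of the batch loss w.r.t. one parameter tensor.
numeric_grad <- function(model, nm, ids, labels, eps = 1e-6) {
  g <- model$params[[nm]]
  g[] <- 0
  for (i in seq_along(g)) {
    up <- model; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- model; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    g[i] <- (model_loss_grads(up, ids, labels)$loss -
               model_loss_grads(dn, ids, labels)$loss) / (2 * eps)
  }
  g
}

# Deterministic-layer model (all dropout off) for gradient checks.
gradcheck_model <- function(seed = 7) {
  lncpair_model(vocab_size = 8, n_embedding = 4, n_hidden = 3, n_dense = 5,
                p_embed_vector = 0, p_embed_weight = 0, p_dropconnect = 0,
                p_dropout = 0, seed = seed)
}

max_rel_err <- function(a, b, floor = 1e-8) {
  max(abs(a - b) / pmax(abs(a) + abs(b), floor))
}
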
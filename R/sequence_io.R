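#' Read a FASTA file into a sequence table
#'
#' Parses a (wrapped or unwrapped) multi-record FASTA file and canonicalizes
#' residues: everything is uppercased, `T` is rewritten to `U` under the RNA
#' alphabet (DNA-alphabet reference FASTA is common for lncRNAs), and any
#' symbol outside the declared alphabet is rewritten to its ambiguity symbol
#' (`N`/`X`) with a warning.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"RNA"` or `"PROTEIN"`.
#' @return A tibble with columns `id`, `residues`, `alphabet`, `length`
#'   (one row per FASTA entry).
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">m1", "acgt"), tf)
#' read_fasta(tf, "RNA")
read_fasta <- function(path, alphabet = c("RNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  keep <- nchar(lines) > 0
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("malformed FASTA: file is empty", call. = FALSE)
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop(sprintf("malformed FASTA: line %d precedes any '>' header", line_no[1]),
         call. = FALSE)
  }
  entry <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  seqs <- vapply(
    split(lines[!is_header], factor(entry[!is_header], levels = seq_along(ids))),
    paste0, character(1), collapse = ""
  )
  empty <- which(nchar(seqs) == 0 | is.na(seqs))
  if (length(empty) > 0) {
    stop(sprintf("malformed FASTA: empty sequence for entry '%s' (header line %d)",
                 ids[empty[1]], line_no[which(is_header)[empty[1]]]), call. = FALSE)
  }
  residues <- canonicalize_residues(unname(seqs), alphabet)
  tibble::tibble(
    id = ids, residues = residues, alphabet = alphabet, length = nchar(residues)
  )
}

#' Write a sequence table to FASTA
#'
#' @param records Tibble with columns `id` and `residues` (as produced by
#'   [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  chunks <- purrr::map2(records$id, records$residues, function(id, s) {
    starts <- seq(1, max(nchar(s), 1), by = width)
    c(paste0(">", id), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  })
  writeLines(unlist(chunks), path)
  invisible(path)
}

#' Load an interaction-pair table
#'
#' Reads a headered TSV with columns `a_id`, `b_id` and optionally `label`
#' (0 = non-interactive, 1 = interactive). Ids are validated against the
#' supplied record tables when given; duplicated `(a_id, b_id)` rows are an
#' error so that label counts stay well defined.
#'
#' @param path Path to the TSV.
#' @param lnc,partner Optional sequence tables used to resolve `a_id` /
#'   `b_id`; an unresolved id is an error.
#' @param positives_only If `TRUE`, all labels are forced to 1 (useful for
#'   databases that only deposit known interactions).
#' @return A tibble with columns `a_id`, `b_id`, `label`.
#' @export
load_pairs <- function(path, lnc = NULL, partner = NULL, positives_only = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("a_id", "b_id") %in% names(tab))) {
    stop("pair table must have columns a_id and b_id", call. = FALSE)
  }
  label <- if (positives_only || !("label" %in% names(tab))) {
    rep(1L, nrow(tab))
  } else {
    as.integer(tab$label)
  }
  if (any(is.na(label)) || !all(label %in% c(0L, 1L))) {
    stop("pair labels must be 0 or 1", call. = FALSE)
  }
  pairs <- tibble::tibble(a_id = tab$a_id, b_id = tab$b_id, label = label)
  validate_pairs(pairs, lnc, partner)
  pairs
}

#' @rdname load_pairs
#' @param pairs A pair tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("a_id", "b_id", "label")], path)
  invisible(path)
}

validate_pairs <- function(pairs, lnc = NULL, partner = NULL) {
  key <- paste(pairs$a_id, pairs$b_id, sep = "\t")
  if (anyDuplicated(key)) {
    dup <- pairs[duplicated(key), ][1, ]
    stop(sprintf("duplicate pair (%s, %s)", dup$a_id, dup$b_id), call. = FALSE)
  }
  if (!is.null(lnc)) {
    bad <- setdiff(pairs$a_id, lnc$id)
    if (length(bad) > 0) stop("unknown id ", bad[1], call. = FALSE)
  }
  if (!is.null(partner)) {
    bad <- setdiff(pairs$b_id, partner$id)
    if (length(bad) > 0) stop("unknown id ", bad[1], call. = FALSE)
  }
  invisible(pairs)
}

#' Assemble a paired interaction corpus
#'
#' Bundles lncRNA records, partner (miRNA or protein) records and a labeled
#' pair table, validating that every pair resolves and that positive and
#' negative pair sets are disjoint.
#'
#' @param lnc,partner Sequence tables (see [read_fasta()]).
#' @param pairs Pair tibble with `a_id`, `b_id`, `label`.
#' @return A `paired_corpus` object (list with elements `lnc`, `partner`,
#'   `pairs`).
#' @export
paired_corpus <- function(lnc, partner, pairs) {
  validate_pairs(pairs, lnc, partner)
  structure(list(lnc = lnc, partner = partner, pairs = pairs),
            class = "paired_corpus")
}

#' @export
print.paired_corpus <- function(x, ...) {
  cat(sprintf(
    "<paired_corpus> %d lncRNAs, %d partners (%s), %d pairs (%d+/%d-)\n",
    nrow(x$lnc), nrow(x$partner), x$partner$alphabet[1] %||% "?",
    nrow(x$pairs), sum(x$pairs$label == 1), sum(x$pairs$label == 0)
  ))
  invisible(x)
}

#' Per-side corpus length statistics
#'
#' @param records A sequence table or a character vector of residue strings.
#' @return A list with `min`, `mean`, `max` sequence lengths in residues.
#' @export
corpus_length_stats <- function(records) {
  len <- if (is.character(records)) nchar(records) else records$length
  if (length(len) == 0) stop("no sequences to summarize", call. = FALSE)
  list(min = min(len), mean = mean(len), max = max(len))
}

#' Knuth--Durstenfeld (Fisher--Yates) shuffle
#'
#' In-place uniform shuffle, iterating from the last element down and swapping
#' with a uniformly drawn earlier position. Applied `n_shuffles` times (the
#' random-pairing scheme for negatives shuffles both id lists 10 times before
#' drawing).
#'
#' @param x A vector.
#' @param n_shuffles Number of shuffle passes.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A permutation of `x`.
#' @export
kd_shuffle <- function(x, n_shuffles = 1, seed = NULL) {
  run <- function() {
    n <- length(x)
    for (rep in seq_len(n_shuffles)) {
      if (n < 2) break
      for (i in n:2) {
        j <- floor(stats::runif(1) * i) + 1 # uniform on 1..i
        tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
      }
    }
    x
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate non-interactive pairs by random pairing
#'
#' Emulates the benchmark construction of negatives: both id lists are
#' shuffled `n_shuffles` times with the Knuth--Durstenfeld algorithm, then
#' random (lncRNA, partner) pairs are drawn and kept provided the pair is not
#' in the positive set; duplicate negatives are also rejected so label counts
#' stay well defined. Rejection sampling is capped at `100 * n` attempts.
#'
#' @param corpus A [paired_corpus()] whose `pairs` are the known positives.
#' @param n Number of negatives to draw.
#' @param n_shuffles Shuffle passes before drawing (default 10).
#' @param seed Integer seed.
#' @return A tibble of `n` pairs with `label = 0`.
#' @export
generate_negatives <- function(corpus, n, n_shuffles = 10, seed = 1) {
  lnc_ids <- corpus$lnc$id
  par_ids <- corpus$partner$id
  pos <- corpus$pairs[corpus$pairs$label == 1, , drop = FALSE]
  capacity <- length(lnc_ids) * length(par_ids) - nrow(pos)
  if (n > capacity) {
    stop(sprintf("requested %d negatives but only %d non-positive pairs exist",
                 n, capacity), call. = FALSE)
  }
  withr::with_seed(seed, {
    la <- kd_shuffle(lnc_ids, n_shuffles)
    lb <- kd_shuffle(par_ids, n_shuffles)
    taken <- new.env(parent = emptyenv())
    for (k in paste(pos$a_id, pos$b_id, sep = "\t")) assign(k, TRUE, envir = taken)
    out_a <- character(n); out_b <- character(n)
    got <- 0L; attempts <- 0L; max_attempts <- 100L * n
    while (got < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("rejection sampling exceeded 100*n attempts", call. = FALSE)
      }
      a <- la[floor(stats::runif(1) * length(la)) + 1]
      b <- lb[floor(stats::runif(1) * length(lb)) + 1]
      key <- paste(a, b, sep = "\t")
      if (!is.null(taken[[key]])) next
      assign(key, TRUE, envir = taken)
      got <- got + 1L
      out_a[got] <- a; out_b[got] <- b
    }
    tibble::tibble(a_id = out_a, b_id = out_b, label = 0L)
  })
}

#' Label-stratified cross-validation folds with validation tagging
#'
#' Partitions pairs into `n_folds` disjoint test folds (stratified by label
#' unless `stratify = FALSE`). Within the training split of each fold,
#' `val_fraction` of pairs (again stratified) are tagged as the validation
#' subset used for early stopping and model selection; these tags are the
#' logical columns `val_f1 ... val_f<n_folds>`.
#'
#' @param pairs Labeled pair tibble.
#' @param n_folds Number of folds (>= 2).
#' @param val_fraction Fraction of each training split tagged as validation.
#' @param seed Integer seed.
#' @param stratify Stratify folds by label?
#' @return `pairs` with an integer `fold` column and `val_f*` logicals.
#' @export
split_folds <- function(pairs, n_folds = 5, val_fraction = 0.1, seed = 1,
                        stratify = TRUE) {
  n <- nrow(pairs)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (n < n_folds) stop("fewer pairs than folds", call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("val_fraction must be in [0, 1)", call. = FALSE)
  }
  withr::with_seed(seed, {
    strata <- if (stratify) pairs$label else rep(0L, n)
    fold <- integer(n)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    val <- matrix(FALSE, n, n_folds)
    for (f in seq_len(n_folds)) {
      for (s in unique(strata)) {
        cand <- which(strata == s & fold != f)
        n_val <- round(val_fraction * length(cand))
        if (n_val > 0) val[cand[sample.int(length(cand), n_val)], f] <- TRUE
      }
    }
    out <- pairs
    out$fold <- fold
    for (f in seq_len(n_folds)) out[[paste0("val_f", f)]] <- val[, f]
    out
  })
}
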
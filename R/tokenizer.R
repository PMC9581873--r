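#' Generate higher-order residues (k-mers) of a sequence
#'
#' Slides a window of size `k` across the sequence with the given stride:
#' overlapping tokens for `stride < k`, non-overlapping for `stride == k`.
#' The token count is exactly `floor((L - k) / stride) + 1`.
#'
#' @param seq A single residue string.
#' @param k Window size (k-mer order), `k >= 1`.
#' @param stride Window step, `1 <= stride <= k`.
#' @return Character vector of k-mer strings.
#' @export
#' @examples
#' generate_kmers("ACGU", k = 2, stride = 1) # "AC" "CG" "GU"
generate_kmers <- function(seq, k, stride = 1) {
  L <- nchar(seq)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (stride < 1 || stride > k) stop("stride must satisfy 1 <= stride <= k", call. = FALSE)
  if (L < k) stop(sprintf("sequence length %d is shorter than k = %d", L, k), call. = FALSE)
  starts <- seq.int(1L, L - k + 1L, by = stride)
  substring(seq, starts, starts + k - 1L)
}

#' Build a full k-mer vocabulary over an alphabet
#'
#' Enumerates all `|alphabet|^k` k-mers in lexicographic order (4^k for RNA)
#' and assigns contiguous integer indices starting at 2; indices 0 and 1 are
#' reserved for `PAD` (tokens overlapping the padding region) and `UNK`
#' (tokens containing an ambiguity symbol). Full enumeration keeps indices
#' corpus-independent.
#'
#' @param alphabet `"RNA"` or `"PROTEIN"`.
#' @param k K-mer order.
#' @param stride Stride stored alongside the vocabulary (default 1,
#'   overlapping tokens).
#' @return A `kmer_vocab` object; its `size` is `|alphabet|^k + 2`.
#' @export
#' @examples
#' kmer_vocabulary("RNA", k = 1)$size # 6
kmer_vocabulary <- function(alphabet = c("RNA", "PROTEIN"), k, stride = 1) {
  alphabet <- match.arg(alphabet)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (stride < 1 || stride > k) stop("stride must satisfy 1 <= stride <= k", call. = FALSE)
  syms <- alphabet_symbols(alphabet)
  kmers <- ""
  for (i in seq_len(k)) kmers <- as.vector(t(outer(kmers, syms, paste0)))
  index_of <- stats::setNames(seq_along(kmers) + 1L, kmers) # PAD=0, UNK=1
  structure(
    list(alphabet = alphabet, k = as.integer(k), stride = as.integer(stride),
         kmers = kmers, index_of = index_of,
         size = length(kmers) + 2L, pad_id = 0L, unk_id = 1L),
    class = "kmer_vocab"
  )
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> %s %d-mers, stride %d, size %d (incl. PAD/UNK)\n",
              x$alphabet, x$k, x$stride, x$size))
  invisible(x)
}

#' Combine per-segment vocabularies into one index space
#'
#' For same-alphabet tasks (lncRNA--miRNA) both segments share one
#' vocabulary. For mixed-alphabet tasks (lncRNA--protein) the partner
#' vocabulary is offset after the lncRNA k-mers so a single embedding table
#' covers both; `PAD`/`UNK` (indices 0/1) are shared.
#'
#' @param lnc_vocab,partner_vocab [kmer_vocabulary()] objects;
#'   `partner_vocab = NULL` means the partner shares `lnc_vocab`.
#' @return A `pair_vocab` object.
#' @export
pair_vocabulary <- function(lnc_vocab, partner_vocab = NULL) {
  shared <- is.null(partner_vocab) ||
    (identical(partner_vocab$alphabet, lnc_vocab$alphabet) &&
     identical(partner_vocab$k, lnc_vocab$k))
  if (shared) {
    structure(list(lnc = lnc_vocab, partner = lnc_vocab,
                   partner_offset = 0L, size = lnc_vocab$size),
              class = "pair_vocab")
  } else {
    offset <- lnc_vocab$size - 2L
    structure(list(lnc = lnc_vocab, partner = partner_vocab,
                   partner_offset = offset,
                   size = lnc_vocab$size + partner_vocab$size - 2L),
              class = "pair_vocab")
  }
}

# Token ids (0-based) for one fixed-length segment. K-mers overlapping the
# pad region map to PAD (0); k-mers containing an ambiguity symbol map to
# UNK (1); the pad rule wins when both apply.
encode_segment <- function(seq, vocab, pad = "-", offset = 0L) {
  kmers <- generate_kmers(seq, vocab$k, vocab$stride)
  ids <- unname(vocab$index_of[kmers])
  miss <- which(is.na(ids))
  if (length(miss) > 0) {
    has_pad <- grepl(pad, kmers[miss], fixed = TRUE)
    has_amb <- grepl(ambiguity_symbol(vocab$alphabet), kmers[miss], fixed = TRUE)
    ids[miss[has_pad]] <- 0L
    ids[miss[!has_pad & has_amb]] <- 1L
    if (any(!has_pad & !has_amb)) {
      stop("token outside vocabulary: ", kmers[miss[!has_pad & !has_amb]][1],
           call. = FALSE)
    }
  }
  ids <- as.integer(ids)
  ids[ids >= 2L] <- ids[ids >= 2L] + as.integer(offset)
  ids
}

#' Tokenize fused sequence pairs
#'
#' Each pair instance is tokenized segment-wise (lncRNA tokens first, partner
#' tokens second; no k-mers span the junction) into 0-based integer ids.
#' All inputs must already be fixed-length so every instance shares the same
#' per-segment token counts.
#'
#' @param lnc_fixed,partner_fixed Fixed-length sequence tables
#'   (see [apply_policy()]).
#' @param pairs Pair tibble with `a_id`, `b_id`, `label`.
#' @param vocab A [pair_vocabulary()] (or a single [kmer_vocabulary()]
#'   shared by both segments).
#' @param pad Padding symbol used by the length policy.
#' @param fuse_then_tokenize Compatibility mode: concatenate the two
#'   residue segments *before* tokenizing, so k-mers may span the junction
#'   (chimeric tokens). Only valid when both segments share one alphabet;
#'   the default tokenizes segment-wise.
#' @return A `tokenized_pairs` object: integer id matrix `ids`
#'   (pairs x tokens), `segments` (per-segment token counts), `labels`,
#'   `vocab_size` and the pair ids.
#' @export
encode_pairs <- function(lnc_fixed, partner_fixed, pairs, vocab, pad = "-",
                         fuse_then_tokenize = FALSE) {
  if (inherits(vocab, "kmer_vocab")) vocab <- pair_vocabulary(vocab)
  stopifnot(inherits(vocab, "pair_vocab"))
  if (fuse_then_tokenize) {
    if (vocab$partner_offset != 0L) {
      stop("fuse_then_tokenize requires both segments to share one alphabet",
           call. = FALSE)
    }
    lnc_map <- stats::setNames(lnc_fixed$residues, lnc_fixed$id)
    par_map <- stats::setNames(partner_fixed$residues, partner_fixed$id)
    fused <- paste0(lnc_map[pairs$a_id], par_map[pairs$b_id])
    ids <- do.call(rbind, lapply(fused, encode_segment, vocab = vocab$lnc,
                                 pad = pad))
    return(structure(
      list(ids = ids, segments = c(lnc = ncol(ids), partner = 0L),
           labels = as.integer(pairs$label),
           a_id = pairs$a_id, b_id = pairs$b_id, vocab_size = vocab$size),
      class = "tokenized_pairs"))
  }
  enc_side <- function(records, v, offset) {
    ids_list <- lapply(records$residues, encode_segment, vocab = v, pad = pad,
                       offset = offset)
    n_tok <- lengths(ids_list)
    if (length(unique(n_tok)) != 1) {
      stop("segments are not fixed-length: apply a length policy first",
           call. = FALSE)
    }
    m <- do.call(rbind, ids_list)
    rownames(m) <- records$id
    m
  }
  lnc_tok <- enc_side(lnc_fixed, vocab$lnc, 0L)
  par_tok <- enc_side(partner_fixed, vocab$partner, vocab$partner_offset)
  miss_a <- setdiff(pairs$a_id, rownames(lnc_tok))
  if (length(miss_a)) stop("unknown id ", miss_a[1], call. = FALSE)
  miss_b <- setdiff(pairs$b_id, rownames(par_tok))
  if (length(miss_b)) stop("unknown id ", miss_b[1], call. = FALSE)
  ids <- cbind(lnc_tok[pairs$a_id, , drop = FALSE],
               par_tok[pairs$b_id, , drop = FALSE])
  rownames(ids) <- NULL
  structure(
    list(ids = ids,
         segments = c(lnc = ncol(lnc_tok), partner = ncol(par_tok)),
         labels = as.integer(pairs$label),
         a_id = pairs$a_id, b_id = pairs$b_id,
         vocab_size = vocab$size),
    class = "tokenized_pairs"
  )
}

#' @export
print.tokenized_pairs <- function(x, ...) {
  cat(sprintf("<tokenized_pairs> %d pairs, %d + %d tokens, vocab %d\n",
              nrow(x$ids), x$segments[["lnc"]], x$segments[["partner"]],
              x$vocab_size))
  invisible(x)
}

# Subset a tokenized dataset by row index.
subset_tokens <- function(data, idx) {
  structure(
    list(ids = data$ids[idx, , drop = FALSE], segments = data$segments,
         labels = data$labels[idx], a_id = data$a_id[idx], b_id = data$b_id[idx],
         vocab_size = data$vocab_size),
    class = "tokenized_pairs"
  )
}

#' Save / load a k-mer vocabulary as plain text
#'
#' Two-column `kmer<TAB>index` table preceded by `#`-prefixed header lines
#' recording alphabet, k and stride; round-trips exactly.
#'
#' @param vocab A [kmer_vocabulary()].
#' @param path File path.
#' @return `write_vocab()` returns `path` invisibly; `read_vocab()` returns
#'   the vocabulary.
#' @export
write_vocab <- function(vocab, path) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  header <- c(paste("# alphabet", vocab$alphabet),
              paste("# k", vocab$k),
              paste("# stride", vocab$stride))
  body <- paste(vocab$kmers, vocab$index_of[vocab$kmers], sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) sub(paste0("# ", key, " "), "", hdr[startsWith(hdr, paste0("# ", key))])
  vocab <- kmer_vocabulary(get("alphabet"), as.integer(get("k")),
                           as.integer(get("stride")))
  body <- lines[!startsWith(lines, "#")]
  parts <- strsplit(body, "\t", fixed = TRUE)
  stored <- stats::setNames(as.integer(vapply(parts, `[[`, "", 2)),
                            vapply(parts, `[[`, "", 1))
  if (!identical(unname(stored[vocab$kmers]), unname(vocab$index_of[vocab$kmers]))) {
    stop("vocabulary file is inconsistent with its header", call. = FALSE)
  }
  vocab
}
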
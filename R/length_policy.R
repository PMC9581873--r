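#' Fixed-length strategy for variable-length sequences
#'
#' Defines how a corpus of variable-length sequences is mapped to a single
#' fixed length. Three classical strategies use corpus statistics — pad all
#' sequences to the maximum length (`"max_pad"`), truncate all to the minimum
#' (`"min_trunc"`), or pad/truncate to the rounded mean (`"avg_hybrid"`) —
#' and three positional sub-sequence strategies keep only the first `X`
#' residues (`"start"`), the last `Y` residues (`"end"`), or their
#' concatenation (`"start_end"`, target length `X + Y`). Padding and
#' truncation act on the end of sequences, the dominant convention in the
#' field.
#'
#' @param strategy One of `"max_pad"`, `"min_trunc"`, `"avg_hybrid"`,
#'   `"start"`, `"end"`, `"start_end"`.
#' @param X Residue budget from the start (for `"start"`, `"start_end"`).
#' @param Y Residue budget from the end (for `"end"`, `"start_end"`).
#' @param pad Padding symbol; must not belong to any residue alphabet.
#' @return A `length_policy` object.
#' @export
#' @examples
#' length_policy("start", X = 20)
#' length_policy("start_end", X = 25, Y = 25)
length_policy <- function(strategy = c("max_pad", "min_trunc", "avg_hybrid",
                                       "start", "end", "start_end"),
                          X = NULL, Y = NULL, pad = "-") {
  strategy <- match.arg(strategy)
  if (nchar(pad) != 1 ||
      pad %in% unlist(lapply(names(.alphabets), alphabet_symbols, with_ambiguity = TRUE))) {
    stop("pad must be a single symbol outside all residue alphabets", call. = FALSE)
  }
  needs_x <- strategy %in% c("start", "start_end")
  needs_y <- strategy %in% c("end", "start_end")
  if (needs_x && (is.null(X) || X < 1)) stop("strategy '", strategy, "' requires X >= 1", call. = FALSE)
  if (needs_y && (is.null(Y) || Y < 1)) stop("strategy '", strategy, "' requires Y >= 1", call. = FALSE)
  structure(
    list(strategy = strategy,
         X = if (needs_x) as.integer(X) else NULL,
         Y = if (needs_y) as.integer(Y) else NULL,
         pad = pad, side = "end"),
    class = "length_policy"
  )
}

#' @export
print.length_policy <- function(x, ...) {
  budget <- paste(c(if (!is.null(x$X)) paste0("X=", x$X),
                    if (!is.null(x$Y)) paste0("Y=", x$Y)), collapse = ", ")
  cat(sprintf("<length_policy> %s%s (pad '%s', %s side)\n",
              x$strategy, if (nzchar(budget)) paste0(" ", budget) else "",
              x$pad, x$side))
  invisible(x)
}

#' Pad sequences to an exact length
#'
#' Appends pad symbols to the end of each sequence until it reaches length
#' `L`. Sequences longer than `L` are an error.
#'
#' @param seq Character vector of residue strings.
#' @param L Target length.
#' @param pad Padding symbol.
#' @return Character vector, every element of length `L`.
#' @export
#' @examples
#' pad_to_length("ACG", 5) # "ACG--"
pad_to_length <- function(seq, L, pad = "-") {
  n <- nchar(seq)
  if (any(n > L)) {
    stop(sprintf("sequence of length %d exceeds target length %d",
                 max(n), L), call. = FALSE)
  }
  paste0(seq, strrep(pad, L - n))
}

#' Truncate sequences to at most a target length
#'
#' Keeps the first `L` residues; shorter sequences are returned unchanged.
#'
#' @inheritParams pad_to_length
#' @return Character vector.
#' @export
#' @examples
#' truncate_to_length("ACGUA", 3) # "ACG"
truncate_to_length <- function(seq, L) {
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  substr(seq, 1L, L)
}

#' Extract a fixed-length positional sub-sequence
#'
#' Under `"start"` keeps the first `X` residues, under `"end"` the last `Y`,
#' and under `"start_end"` the first `X` concatenated with the last `Y`.
#' Sequences shorter than the budget are end-padded with the policy's pad
#' symbol so the output always has the contracted length (`X`, `Y`, or
#' `X + Y`); when `X + Y` exceeds the sequence length the start and end
#' windows overlap, which is permitted with a warning.
#'
#' @param seq Character vector of residue strings.
#' @param policy A [length_policy()] with a sub-sequence strategy.
#' @return Character vector of fixed-length sub-sequences.
#' @export
#' @examples
#' take_region("ABCDEFGH", length_policy("start_end", X = 3, Y = 2))
take_region <- function(seq, policy) {
  if (!inherits(policy, "length_policy") ||
      !policy$strategy %in% c("start", "end", "start_end")) {
    stop("take_region requires a start/end/start_end policy", call. = FALSE)
  }
  n <- nchar(seq)
  out <- switch(policy$strategy,
    start = substr(seq, 1L, policy$X),
    end   = substr(seq, pmax(1L, n - policy$Y + 1L), n),
    start_end = {
      if (any(n < policy$X + policy$Y)) {
        warning("start and end windows overlap for sequences shorter than X + Y",
                call. = FALSE)
      }
      paste0(substr(seq, 1L, policy$X),
             substr(seq, pmax(1L, n - policy$Y + 1L), n))
    }
  )
  target <- switch(policy$strategy,
    start = policy$X, end = policy$Y, start_end = policy$X + policy$Y)
  pad_to_length(out, target, policy$pad)
}

# Round-half-up; the hybrid policy's target for the corpus mean length.
round_half_up <- function(x) floor(x + 0.5)

policy_target_length <- function(policy, stats = NULL) {
  switch(policy$strategy,
    start     = policy$X,
    end       = policy$Y,
    start_end = policy$X + policy$Y,
    {
      if (is.null(stats)) {
        stop("policy '", policy$strategy, "' needs corpus length stats",
             call. = FALSE)
      }
      switch(policy$strategy,
        max_pad    = stats$max,
        min_trunc  = stats$min,
        avg_hybrid = round_half_up(stats$mean))
    })
}

#' Apply a length policy to a sequence table
#'
#' Transforms every record to the policy's fixed target length. Statistics
#' for the corpus-driven strategies must come from the training split only
#' (to avoid leakage); held-out sequences longer than the target are
#' truncated and shorter ones padded, so the fixed-length contract holds for
#' unseen data too.
#'
#' @param records Sequence table (see [read_fasta()]).
#' @param policy A [length_policy()].
#' @param stats Training-split [corpus_length_stats()]; required for
#'   `"max_pad"`, `"min_trunc"`, `"avg_hybrid"`.
#' @return `records` with `residues` replaced by fixed-length strings and
#'   `length` updated (all equal).
#' @export
apply_policy <- function(records, policy, stats = NULL) {
  out <- records
  if (policy$strategy %in% c("start", "end", "start_end")) {
    out$residues <- take_region(records$residues, policy)
  } else {
    L <- policy_target_length(policy, stats)
    out$residues <- pad_to_length(truncate_to_length(records$residues, L), L, policy$pad)
  }
  out$length <- nchar(out$residues)
  out
}

#' Fuse a fixed-length lncRNA segment with a partner segment
#'
#' A pair instance keeps its two segments ordered and distinct (lncRNA first)
#' so that downstream tokenization never creates k-mers spanning the
#' junction.
#'
#' @param lnc_fixed,partner_fixed Fixed-length residue strings.
#' @return A `fused_pair` list with elements `lnc`, `partner`, and
#'   `lengths`.
#' @export
fuse_pair <- function(lnc_fixed, partner_fixed) {
  structure(
    list(lnc = lnc_fixed, partner = partner_fixed,
         lengths = c(lnc = nchar(lnc_fixed), partner = nchar(partner_fixed))),
    class = "fused_pair"
  )
}
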
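# Residue alphabets. RNA sequences are canonicalized to {A,C,G,U} with N as
# the ambiguity symbol; proteins use the 20 canonical amino acids with X.
.alphabets <- list(
  RNA     = c("A", "C", "G", "U"),
  PROTEIN = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

.ambiguity <- c(RNA = "N", PROTEIN = "X")

#' Residue symbols of an alphabet
#'
#' @param alphabet `"RNA"` or `"PROTEIN"`.
#' @param with_ambiguity Also include the ambiguity symbol (`N` for RNA,
#'   `X` for protein)?
#' @return Character vector of single-residue symbols.
#' @export
#' @examples
#' alphabet_symbols("RNA")
alphabet_symbols <- function(alphabet = c("RNA", "PROTEIN"), with_ambiguity = FALSE) {
  alphabet <- match.arg(alphabet)
  syms <- .alphabets[[alphabet]]
  if (with_ambiguity) syms <- c(syms, .ambiguity[[alphabet]])
  syms
}

#' @rdname alphabet_symbols
#' @export
ambiguity_symbol <- function(alphabet = c("RNA", "PROTEIN")) {
  alphabet <- match.arg(alphabet)
  unname(.ambiguity[[alphabet]])
}

# Uppercase, map T->U for RNA, rewrite out-of-alphabet symbols to the
# ambiguity symbol. Warns once with the total number of rewritten residues.
canonicalize_residues <- function(x, alphabet) {
  x <- toupper(x)
  if (alphabet == "RNA") x <- chartr("T", "U", x)
  allowed <- paste0(alphabet_symbols(alphabet, with_ambiguity = TRUE), collapse = "")
  pattern <- sprintf("[^%s]", allowed)
  n_bad <- sum(nchar(x) - nchar(gsub(pattern, "", x)))
  if (n_bad > 0) {
    warning(sprintf(
      "%d residue(s) outside the %s alphabet rewritten to '%s'",
      n_bad, alphabet, ambiguity_symbol(alphabet)
    ), call. = FALSE)
    x <- gsub(pattern, ambiguity_symbol(alphabet), x)
  }
  x
}
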
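#' Binary-classifier evaluation report
#'
#' Computes the confusion counts at the given probability threshold and the
#' seven standard metrics: accuracy, specificity (true-negative rate),
#' sensitivity (recall), precision, F1, Matthews correlation coefficient
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' and AUROC via the Mann--Whitney rank statistic with midranks for ties
#' (the probability a random positive is scored above a random negative).
#' A metric whose denominator is zero is reported as 0 and flagged in the
#' `undefined` column, so large sweeps keep running on degenerate folds.
#'
#' @param labels Integer 0/1 labels.
#' @param probs Predicted interactive-class probabilities (a vector, or a
#'   two-column probability matrix whose second column is used).
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row tibble with columns `TP`, `TN`, `FP`, `FN`, `ACC`,
#'   `SPE`, `SEN`, `PRE`, `F1`, `MCC`, `AUROC`, and `undefined`
#'   (comma-separated names of flagged metrics, `""` if none).
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))
compute_metrics <- function(labels, probs, threshold = 0.5) {
  if (is.matrix(probs)) probs <- probs[, ncol(probs)]
  if (length(labels) != length(probs)) {
    stop("labels and probabilities differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  pred <- as.integer(probs >= threshold)
  TP <- sum(pred == 1 & labels == 1)
  TN <- sum(pred == 0 & labels == 0)
  FP <- sum(pred == 1 & labels == 0)
  FN <- sum(pred == 0 & labels == 1)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      undef <<- c(undef, name)
      0
    } else num / den
  }
  ACC <- ratio(TP + TN, TP + TN + FP + FN, "ACC")
  SPE <- ratio(TN, TN + FP, "SPE")
  SEN <- ratio(TP, TP + FN, "SEN")
  PRE <- ratio(TP, TP + FP, "PRE")
  F1 <- ratio(2 * PRE * SEN, PRE + SEN, "F1")
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  MCC <- if (mcc_den == 0) {
    undef <- c(undef, "MCC")
    0
  } else (TP * TN - FP * FN) / mcc_den
  nP <- sum(labels == 1); nN <- sum(labels == 0)
  AUROC <- if (nP == 0 || nN == 0) {
    undef <- c(undef, "AUROC")
    0
  } else {
    r <- rank(probs, ties.method = "average")
    (sum(r[labels == 1]) - nP * (nP + 1) / 2) / (nP * nN)
  }
  tibble::tibble(TP = TP, TN = TN, FP = FP, FN = FN,
                 ACC = ACC, SPE = SPE, SEN = SEN, PRE = PRE, F1 = F1,
                 MCC = MCC, AUROC = AUROC,
                 undefined = paste(unique(undef), collapse = ","))
}

#' Write a metrics report as TSV and JSON
#'
#' @param report A [compute_metrics()] row (or several).
#' @param path_prefix Files `<prefix>.tsv` and `<prefix>.json` are written.
#' @return The two paths, invisibly.
#' @export
write_metrics <- function(report, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  fmt <- report
  num <- vapply(fmt, is.numeric, logical(1)) & !names(fmt) %in% c("TP", "TN", "FP", "FN")
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.4f", x))
  readr::write_tsv(fmt, tsv)
  jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
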
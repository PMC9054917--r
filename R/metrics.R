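#' Multi-label average precision
#'
#' For each instance, labels are ranked by decreasing score (rank 1 =
#' highest score; ties broken toward the smaller label index). For every
#' relevant label the fraction of relevant labels ranked at or above it is
#' computed; the instance value is the mean of these fractions over its
#' relevant labels, and the metric is the mean over instances that have at
#' least one relevant label. Instances with an empty relevant set are
#' skipped (the per-instance normalizer is undefined) and counted.
#'
#' @param S n x L score matrix.
#' @param Ytrue n x L true labels in \{-1, +1\}.
#' @return List: \code{value} in \code{[0, 1]}, \code{nEvaluated},
#'   \code{nSkipped}.
#' @examples
#' S <- rbind(c(0.9, 0.7, 0.5))
#' Y <- rbind(c(1, -1, 1))
#' averagePrecision(S, Y)$value  # (1/2) * (1/1 + 2/3) = 5/6
#' @export
averagePrecision <- function(S, Ytrue) {
  S <- as.matrix(S)
  Ytrue <- as.matrix(Ytrue)
  if (!all(dim(S) == dim(Ytrue))) stop("score and label shapes differ")
  if (any(!is.finite(S))) stop("scores must be finite")
  n <- nrow(S)
  vals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    rel <- which(Ytrue[i, ] == 1)
    if (length(rel) == 0) next
    # rank 1 = largest score; ties -> smaller label index
    rk <- integer(ncol(S))
    rk[order(-S[i, ], seq_len(ncol(S)))] <- seq_len(ncol(S))
    vals[i] <- mean(vapply(rel, function(j)
      sum(rk[rel] <= rk[j]) / rk[j], numeric(1)))
  }
  keep <- !is.na(vals)
  if (!any(keep)) stop("no instance has a relevant label; metric undefined")
  list(value = mean(vals[keep]), nEvaluated = sum(keep),
       nSkipped = sum(!keep))
}

#' Per-label confusion counts
#'
#' @param Ypred,Ytrue n x L matrices with entries in \{-1, +1\}.
#' @return Data frame with one row per label and columns \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}.
#' @export
confusionCounts <- function(Ypred, Ytrue) {
  Ypred <- as.matrix(Ypred)
  Ytrue <- as.matrix(Ytrue)
  if (!all(dim(Ypred) == dim(Ytrue))) stop("shapes differ")
  if (!all(Ypred %in% c(-1, 1)) || !all(Ytrue %in% c(-1, 1)))
    stop("entries must be in {-1, +1}")
  data.frame(
    label = seq_len(ncol(Ytrue)),
    tp = colSums(Ypred == 1 & Ytrue == 1),
    fp = colSums(Ypred == 1 & Ytrue == -1),
    fn = colSums(Ypred == -1 & Ytrue == 1),
    tn = colSums(Ypred == -1 & Ytrue == -1)
  )
}

.f1 <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  ifelse(den == 0, 0, 2 * tp / den)
}

#' Micro-averaged F1
#'
#' F1 of the counts pooled over all labels:
#' \eqn{2\sum tp / (2\sum tp + \sum fp + \sum fn)}; defined as 0 when the
#' denominator vanishes.
#'
#' @param counts confusion counts from [confusionCounts()].
#' @return Scalar in \code{[0, 1]}.
#' @export
f1Micro <- function(counts) {
  .f1(sum(counts$tp), sum(counts$fp), sum(counts$fn))
}

#' Macro-averaged F1
#'
#' Mean of the per-label F1 values; a label whose denominator vanishes
#' (never present and never predicted) contributes 0.
#'
#' @param counts confusion counts from [confusionCounts()].
#' @return Scalar in \code{[0, 1]}.
#' @export
f1Macro <- function(counts) {
  mean(.f1(counts$tp, counts$fp, counts$fn))
}

#' Evaluate scores against true labels
#'
#' Computes the three multi-label metrics used throughout the package:
#' average precision from the raw scores, and micro-/macro-F1 from the
#' thresholded labels.
#'
#' @param S score matrix.
#' @param Ytrue true labels in \{-1, +1\}.
#' @return Named numeric vector \code{c(avgprec, micro_f1, macro_f1)}.
#' @export
evaluateScores <- function(S, Ytrue) {
  cc <- confusionCounts(thresholdLabels(S), Ytrue)
  c(avgprec = averagePrecision(S, Ytrue)$value,
    micro_f1 = f1Micro(cc),
    macro_f1 = f1Macro(cc))
}

#' Write metric records as tidy long-format CSV
#'
#' @param records data frame with columns run_id/repetition, algorithm,
#'   labeling_rate, metric, value (as produced by [runProtocol()]).
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeRecords <- function(records, path) {
  write.table(records, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a records CSV written by [writeRecords()]
#'
#' @param path CSV path.
#' @return Data frame of records.
#' @export
readRecords <- function(path) {
  read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
}
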
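#' F1 score from precision and recall
#'
#' The harmonic mean \code{2 P R / (P + R)}, defined as 0 when both
#' precision and recall are 0.
#'
#' @param precision,recall Fractions in \code{[0, 1]} (vectorized).
#' @return Numeric vector of F1 values.
#' @export
f1Score <- function(precision, recall) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1,
          na.rm = TRUE))
    stop("precision and recall must lie in [0, 1]")
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' F1 of the all-positive baseline classifier
#'
#' Predicting every pair positive gives precision equal to the positive
#' prevalence and recall 1, hence \code{F1 = 2 p / (1 + p)}.  This is the
#' natural "random" performance floor for imbalanced EP data: at a 1:20
#' positive:negative ratio (prevalence 1/21) it equals 1/11.
#'
#' @param posFraction Positive-class prevalence in \code{(0, 1]}.
#' @return The baseline F1.
#' @examples
#' allPositiveF1(1 / 21)  # 1/11
#' @export
allPositiveF1 <- function(posFraction) {
  if (any(posFraction <= 0 | posFraction > 1))
    stop("posFraction must lie in (0, 1]")
  2 * posFraction / (1 + posFraction)
}

## Mann-Whitney AUROC with midranks for tied scores.
.auroc <- function(labels, scores) {
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

## Area under the precision-recall curve as average precision: sum over
## distinct score thresholds (descending) of delta-recall times the
## precision at that threshold.  Tied scores enter as one threshold.
.auprc <- function(labels, scores) {
  np <- sum(labels == 1L)
  if (np == 0L || all(labels == 1L)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  cuts <- which(diff(sc) != 0)
  ends <- c(cuts, length(sc))
  tp <- cumsum(lab)[ends]
  pp <- ends
  prec <- tp / pp
  rec <- tp / np
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics from scores
#'
#' Computes precision, recall and F1 by thresholding the scores, plus
#' ranking-based AUROC (Mann-Whitney with midranks for ties) and AUPRC
#' (average precision; tied scores share one threshold).  Conventions:
#' precision is 0 when nothing is predicted positive, recall is 0 when
#' there are no positive labels, F1 is 0 when precision and recall are
#' both 0.  With single-class labels AUROC and AUPRC are undefined and
#' returned as \code{NA} while the thresholded metrics are still
#' computed.
#'
#' @param labels Binary vector (0/1).
#' @param scores Numeric scores, higher meaning more positive.
#' @param threshold Score threshold for the positive call (default 0.5,
#'   appropriate for probability-scale scores).
#' @return A named list: \code{precision}, \code{recall}, \code{f1},
#'   \code{auroc}, \code{auprc}.
#' @examples
#' computeMetrics(c(1, 0, 0), c(0.9, 0.8, 0.1))
#' @export
computeMetrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), length(labels) >= 1L)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  pp <- sum(pred == 1L)
  ap <- sum(labels == 1L)
  precision <- if (pp > 0) tp / pp else 0
  recall <- if (ap > 0) tp / ap else 0
  list(precision = precision, recall = recall,
       f1 = f1Score(precision, recall),
       auroc = .auroc(labels, scores),
       auprc = .auprc(labels, scores))
}
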
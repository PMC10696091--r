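#' Area under the ROC curve (rank-based, half credit for ties)
#'
#' Equivalent to the Mann-Whitney probability that a random positive
#' outranks a random negative, counting ties as one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or 0/1) true-positive indicators.
#' @return AUROC in `[0, 1]`; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # average ranks give half credit on ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Computed blockwise over tied-score groups with the continuous
#' interpolation of precision within each block (positives assumed spread
#' uniformly through the block), so tied scores receive half credit in
#' the same spirit as [auroc()]. For a perfect scorer the area is exactly
#' 1; for a random scorer it approaches the positive fraction.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`; `NA` if there are no positives.
#' @export
auprc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  if (P == 0 || length(scores) == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  blocks <- rle(s)$lengths
  ends <- cumsum(blocks)
  starts <- ends - blocks + 1L
  cum_tp <- cumsum(y)
  area <- 0
  for (j in seq_along(blocks)) {
    t <- blocks[j]
    p <- cum_tp[ends[j]] - if (j > 1) cum_tp[ends[j - 1]] else 0
    if (p == 0) next
    tp0 <- if (j > 1) cum_tp[ends[j - 1]] else 0
    n0 <- if (j > 1) ends[j - 1] else 0L
    # integral over x in (0,1] of precision (tp0 + p x) / (n0 + t x),
    # times the recall increment p / P
    int <- if (n0 == 0) {
      p / t
    } else {
      p / t + (tp0 - n0 * p / t) * log((n0 + t) / n0) / t
    }
    area <- area + (p / P) * int
  }
  area
}

#' One-vs-all classifier evaluation
#'
#' @param scores Matrix of class probabilities (columns named by class).
#' @param labels Character vector of true class labels.
#' @return A list with `metrics` (tibble: class, auprc, auroc; `NA` for a
#'   class absent from `labels`) and `curves` (list of per-class tibbles
#'   with ROC and PR coordinates).
#' @export
evaluate_classifier_scores <- function(scores, labels) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)),
            nrow(scores) == length(labels))
  classes <- colnames(scores)
  metrics <- tibble::tibble(
    class = classes,
    auprc = vapply(classes, function(k) auprc(scores[, k], labels == k),
                   numeric(1), USE.NAMES = FALSE),
    auroc = vapply(classes, function(k) auroc(scores[, k], labels == k),
                   numeric(1), USE.NAMES = FALSE))
  curves <- lapply(stats::setNames(classes, classes), function(k) {
    pos <- labels == k
    if (!any(pos) || all(pos)) return(NULL)
    o <- order(scores[, k], decreasing = TRUE)
    tp <- cumsum(pos[o]); fp <- cumsum(!pos[o])
    tibble::tibble(threshold = scores[o, k],
                   tpr = tp / sum(pos), fpr = fp / sum(!pos),
                   precision = tp / (tp + fp), recall = tp / sum(pos))
  })
  list(metrics = metrics, curves = curves)
}
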
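#' Gini index of a binary classifier's continuous scores
#'
#' The Gini index is `2 * AUROC - 1` (Somers' D), where AUROC is the
#' probability that a randomly chosen positive outranks a randomly chosen
#' negative, counting ties as 1/2 (the Mann-Whitney convention). A value of
#' 0 means classification no better than chance; 1 is a perfect ranking;
#' negative values mean systematically reversed ranking. Computed via
#' midranks, so it is exactly the pair-counting statistic and invariant
#' under any strictly increasing transform of the scores.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric vector of the same length, higher = more positive
#'   (label-1) like; must be finite.
#' @return Gini index in `[-1, 1]`.
#' @export
#' @examples
#' compute_gini(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)) # 1: perfect
#' compute_gini(c(1, 1, 0, 0), c(0.5, 0.5, 0.5, 0.5)) # 0: chance
compute_gini <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length")
  }
  if (anyNA(labels) || anyNA(scores) || any(!is.finite(scores))) {
    stop("labels and scores must be finite and non-missing")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("undefined Gini: both classes must be present")
  }
  r <- rank(scores) # midranks handle ties as 1/2
  auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  2 * auroc - 1
}

#' Empirical null-hypothesis p-value from a Gini distribution
#'
#' The fraction of cross-validation (or bootstrap) Gini values at or below
#' 0 -- the empirical probability mass at chance-or-worse performance.
#' Missing values (folds whose CV set held a single class) are excluded
#' from the denominator.
#'
#' @param gini_values numeric vector of Gini indices (may contain `NA`).
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' stage3_pvalue(c(0.1, 0.2, 0.3, 0.4))   # 0
#' stage3_pvalue(c(-0.1, 0, 0.2, 0.3))    # 0.5
stage3_pvalue <- function(gini_values) {
  g <- gini_values[!is.na(gini_values)]
  if (!length(g)) stop("empty Gini distribution")
  mean(g <= 0)
}
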
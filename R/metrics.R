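as_label_vector <- function(x) {
  if (inherits(x, "ClusterLabels")) x$labels else as.vector(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the two
#' labelings:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - [\sum_i\binom{a_i}{2}
#'   \sum_j\binom{b_j}{2}]/\binom{n}{2}}{\frac12[\sum_i\binom{a_i}{2} +
#'   \sum_j\binom{b_j}{2}] - [\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}]/
#'   \binom{n}{2}}}
#' where \eqn{n_{ij}} are the table counts and \eqn{a_i}, \eqn{b_j} its
#' margins. All binomial coefficients are integers below 2^53 for any
#' realistic cell count, so the arithmetic is exact up to the final
#' division. When the expected index equals the maximum index the formula is
#' 0/0 (both partitions trivial, e.g. all cells in one cluster); by
#' convention the result is then 1 if the partitions are identical as set
#' partitions and 0 otherwise.
#'
#' @param A,B partitions: [ClusterLabels] or plain vectors of equal length.
#' @return a number <= 1; 1 means identical partitions, about 0 chance
#'   agreement.
#' @export
adjusted_rand_index <- function(A, B) {
  a <- as_label_vector(A)
  b <- as_label_vector(B)
  if (length(a) != length(b))
    stopf("partitions have different lengths: %d vs %d",
          length(a), length(b))
  n <- length(a)
  same_partition <- identical(match(a, unique(a)), match(b, unique(b)))

  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_nij <- sum(choose2(as.numeric(tab)))
  sum_ai <- sum(choose2(as.numeric(rowSums(tab))))
  sum_bj <- sum(choose2(as.numeric(colSums(tab))))
  n2 <- choose2(n)

  expected <- sum_ai * sum_bj / n2
  max_index <- (sum_ai + sum_bj) / 2
  if (max_index == expected)
    return(if (same_partition) 1 else 0)
  (sum_nij - expected) / (max_index - expected)
}

#' Pearson correlation between C-scores and ARIs
#'
#' Diagnostic mirroring the validity analysis of the scoring index: across
#' repeated clusterings of one data set, lower C-scores should accompany
#' higher ARIs, i.e. the correlation should be negative.
#'
#' @param pairs a 2-column matrix/data.frame (C-score, ARI), or a numeric
#'   vector of C-scores when `ari` is supplied.
#' @param ari optional numeric vector of ARI values.
#' @return the Pearson correlation coefficient.
#' @export
score_ari_correlation <- function(pairs, ari = NULL) {
  if (is.null(ari)) {
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stopf("'pairs' must have two columns")
    x <- pairs[, 1L]; y <- pairs[, 2L]
  } else {
    x <- as.numeric(pairs); y <- as.numeric(ari)
  }
  if (length(x) != length(y)) stopf("coordinate lengths differ")
  if (length(x) < 3L) stopf("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined: a coordinate is constant")
  stats::cor(x, y)
}
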
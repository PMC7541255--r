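PREPROCESS_METHODS <- c("log", "zscore", "none", "sctransform")

new_preprocessed <- function(values, method, parent) {
  dimnames(values) <- dimnames(parent$values)
  structure(list(values = values,
                 method = method,
                 units = parent$units,
                 # detection on the untransformed scale, used by the SC3
                 # gene filter downstream of any transform
                 detection = rowSums(parent$values > 0)),
            class = "PreprocessedMatrix")
}

#' @export
print.PreprocessedMatrix <- function(x, ...) {
  cat(sprintf("PreprocessedMatrix (%s): %d genes x %d cells\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.PreprocessedMatrix <- function(x) dim(x$values)

#' Preprocess an expression matrix
#'
#' Dispatches to one of the four candidate preprocessing methods compared by
#' the selection driver:
#' \describe{
#'   \item{log}{x' = log2(x + 1), elementwise.}
#'   \item{zscore}{per-gene standardization x' = (x - mu_i) / sigma_i with the
#'     sample (n-1) standard deviation; constant genes (sigma_i = 0) map to
#'     all-zero rows so every method keeps identical dimensions.}
#'   \item{none}{identity.}
#'   \item{sctransform}{simplified negative-binomial Pearson residuals, see
#'     [sctransform_like()].}
#' }
#' All methods preserve shape and gene/cell ids, and log and z-score are
#' monotone (rank-preserving) within each non-constant gene.
#'
#' @param M an [ExpressionMatrix].
#' @param method one of `"log"`, `"zscore"`, `"none"`, `"sctransform"`.
#' @param ... passed to the method-specific transform.
#' @return a `PreprocessedMatrix` with fields `values`, `method`, `units`,
#'   and `detection` (per-gene count of cells with untransformed value > 0).
#' @export
preprocess <- function(M, method = PREPROCESS_METHODS, ...) {
  method <- match.arg(method)
  switch(method,
         log = log_transform(M),
         zscore = zscore_transform(M, ...),
         none = no_transform(M),
         sctransform = sctransform_like(M, ...))
}

#' @rdname preprocess
#' @export
log_transform <- function(M) {
  stopifnot(inherits(M, "ExpressionMatrix"))
  new_preprocessed(log2(M$values + 1), "log", M)
}

#' @rdname preprocess
#' @param sd_denominator `"n-1"` (sample standard deviation, default) or
#'   `"n"` (population).
#' @export
zscore_transform <- function(M, sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(M, "ExpressionMatrix"))
  sd_denominator <- match.arg(sd_denominator)
  x <- M$values
  n <- ncol(x)
  mu <- rowMeans(x)
  centred <- x - mu
  ss <- rowSums(centred^2)
  denom <- if (sd_denominator == "n-1") max(n - 1L, 1L) else n
  sigma <- sqrt(ss / denom)
  out <- centred / ifelse(sigma > 0, sigma, 1)
  out[sigma == 0, ] <- 0
  new_preprocessed(out, "zscore", M)
}

#' @rdname preprocess
#' @export
no_transform <- function(M) {
  stopifnot(inherits(M, "ExpressionMatrix"))
  new_preprocessed(M$values, "none", M)
}

#' Simplified negative-binomial Pearson-residual transform
#'
#' A variance-stabilizing transform in the spirit of sctransform, reduced to
#' its essential statistical content and kept behind the same interface so a
#' faithful regularized-regression port could be swapped in. For gene i and
#' cell j with library size \eqn{s_j = \sum_i x_{ij}} the expected count
#' under a multinomial null is \eqn{\mu_{ij} = s_j \cdot \sum_j x_{ij} /
#' \sum_j s_j}; the returned value is the NB Pearson residual
#' \deqn{r_{ij} = (x_{ij} - \mu_{ij}) / \sqrt{\mu_{ij} + \mu_{ij}^2/\theta_i}}
#' with the per-gene dispersion \eqn{\theta_i} estimated by method of
#' moments (infinite, i.e. Poisson, when no overdispersion is detected),
#' floored at `theta_min`, and residuals clipped to \eqn{\pm\sqrt{n}}.
#'
#' @param M an [ExpressionMatrix] of count-like (nonnegative) values.
#' @param theta_min floor on the per-gene NB dispersion estimate.
#' @return a `PreprocessedMatrix` with `method = "sctransform"`.
#' @export
sctransform_like <- function(M, theta_min = 0.01) {
  stopifnot(inherits(M, "ExpressionMatrix"))
  x <- M$values
  n <- ncol(x)
  s <- colSums(x)
  total <- sum(s)
  if (total == 0)
    stopf("cannot compute residuals: all library sizes are zero")
  p <- rowSums(x) / total
  mu <- p %o% s

  # method-of-moments theta: excess of squared residuals over the Poisson
  # variance, gene by gene; non-positive excess means no overdispersion
  sq_resid <- rowSums((x - mu)^2)
  excess <- sq_resid - rowSums(mu)
  theta <- ifelse(excess > 0, rowSums(mu^2) / excess, Inf)
  theta <- pmax(theta, theta_min)

  denom <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / denom
  r[mu == 0] <- 0                      # all-zero genes: residual defined as 0
  clip <- sqrt(n)
  r <- pmin(pmax(r, -clip), clip)
  new_preprocessed(r, "sctransform", M)
}
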
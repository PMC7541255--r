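#' Cluster labels
#'
#' A clustering result: one integer cluster id per cell, ids in
#' `1..num_clusters`.
#'
#' @param labels integer vector of cluster ids.
#' @param num_clusters number of clusters the ids range over; defaults to
#'   `max(labels)`.
#' @return an object of class `ClusterLabels`.
#' @export
ClusterLabels <- function(labels, num_clusters = max(labels)) {
  labels <- as.integer(labels)
  num_clusters <- check_count(num_clusters, "num_clusters")
  if (length(labels) == 0L) stopf("empty labeling")
  if (anyNA(labels) || any(labels < 1L) || any(labels > num_clusters))
    stopf("labels must lie in 1..%d", num_clusters)
  structure(list(labels = labels, num_clusters = num_clusters),
            class = "ClusterLabels")
}

#' @export
print.ClusterLabels <- function(x, ...) {
  cat(sprintf("ClusterLabels: %d cells, %d clusters (%d occupied)\n",
              length(x$labels), x$num_clusters, length(unique(x$labels))))
  invisible(x)
}

#' Consensus (co-association) matrix
#'
#' Symmetric n x n matrix whose (i, j) entry is the fraction of ensemble
#' clusterings placing cells i and j in the same cluster; entries in
#' \[0, 1\], unit diagonal.
#'
#' @param values numeric n x n matrix.
#' @param cell_ids optional cell identifiers (defaults to existing dimnames).
#' @return an object of class `ConsensusMatrix`.
#' @export
ConsensusMatrix <- function(values, cell_ids = NULL) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stopf("'values' must be a square matrix")
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stopf("consensus values must lie in [0, 1]")
  if (max(abs(values - t(values))) > 1e-12)
    stopf("consensus matrix must be symmetric")
  if (max(abs(diag(values) - 1)) > 1e-12)
    stopf("consensus matrix must have unit diagonal")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- list(cell_ids, cell_ids)
  structure(list(values = values, cell_ids = as.character(cell_ids)),
            class = "ConsensusMatrix")
}

#' @export
print.ConsensusMatrix <- function(x, ...) {
  cat(sprintf("ConsensusMatrix: %d cells\n", nrow(x$values)))
  invisible(x)
}

#' Write or read a consensus matrix as TSV
#'
#' n x n values with cell ids as both header and first column, full double
#' precision, so graph scoring can be exercised independently of the
#' clustering engine.
#'
#' @param C a [ConsensusMatrix].
#' @param path file path.
#' @export
write_consensus <- function(C, path) {
  stopifnot(inherits(C, "ConsensusMatrix"))
  v <- C$values
  chr <- matrix(fmt_full(v), nrow(v), ncol(v))
  writeLines(c(paste(c("cell_id", colnames(v)), collapse = "\t"),
               paste(rownames(v), apply(chr, 1L, paste, collapse = "\t"),
                     sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_consensus
#' @export
read_consensus <- function(path) {
  parsed <- parse_dense(path, "\t")
  ConsensusMatrix(parsed$values, cell_ids = parsed$cell_ids)
}

#' SC3-style gene filter
#'
#' Removes genes detected (untransformed value > 0) in fewer than
#' `lower_pct * n` or more than `upper_pct * n` cells — the standard
#' rare-and-ubiquitous filter of the SC3 workflow. Detection counts are
#' taken on the raw scale regardless of the transform applied, so all four
#' preprocessing methods see the same gene set.
#'
#' @param P a `PreprocessedMatrix` (from [preprocess()]).
#' @param lower_pct,upper_pct detection-fraction bounds, defaults 0.06 and
#'   0.94 as in SC3.
#' @return a `PreprocessedMatrix` restricted to the surviving genes.
#' @export
filter_genes <- function(P, lower_pct = 0.06, upper_pct = 0.94) {
  stopifnot(inherits(P, "PreprocessedMatrix"))
  check_fraction(lower_pct, "lower_pct")
  check_fraction(upper_pct, "upper_pct")
  if (lower_pct >= upper_pct) stopf("need lower_pct < upper_pct")
  n <- ncol(P$values)
  keep <- P$detection >= lower_pct * n & P$detection <= upper_pct * n
  if (!any(keep))
    stopf(paste("gene filter removed every gene;",
                "relax lower_pct/upper_pct (currently %g/%g)"),
          lower_pct, upper_pct)
  out <- P
  out$values <- P$values[keep, , drop = FALSE]
  out$detection <- P$detection[keep]
  out
}

#' Cell-cell distance matrix
#'
#' The three distances of the SC3 ensemble: Euclidean distance between cell
#' columns, and 1 - Pearson / 1 - Spearman correlation. Spearman is Pearson
#' on per-column ranks (average ranks for ties). A zero-variance cell column
#' has undefined correlation; its distance to every other cell is defined as
#' 1 (the uninformative midpoint of \[0, 2\]).
#'
#' @param P a `PreprocessedMatrix`.
#' @param metric one of `"euclidean"`, `"pearson"`, `"spearman"`.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
cell_distances <- function(P, metric = c("euclidean", "pearson", "spearman")) {
  metric <- match.arg(metric)
  x <- P$values
  if (ncol(x) < 2L) stopf("need at least 2 cells")
  if (metric == "euclidean") {
    D <- as.matrix(stats::dist(t(x)))
  } else {
    if (metric == "spearman") x <- apply(x, 2L, rank)
    sds <- apply(x, 2L, stats::sd)
    r <- suppressWarnings(stats::cor(x))
    r[sds == 0, ] <- 0
    r[, sds == 0] <- 0
    D <- 1 - r
    diag(D) <- 0
  }
  dimnames(D) <- list(colnames(P$values), colnames(P$values))
  D
}

#' Spectral embedding of a distance matrix
#'
#' The two SC3 transformations of a distance matrix before k-means:
#' `"pca"` takes the first `d` principal components of the (column-centered)
#' distance matrix; `"laplacian"` takes the `d` eigenvectors with smallest
#' eigenvalue of the symmetric normalized graph Laplacian of the similarity
#' kernel `exp(-D / max(D))`.
#'
#' @param D symmetric n x n distance matrix.
#' @param kind `"pca"` or `"laplacian"`.
#' @param d embedding dimension, `d <= n`.
#' @return n x d numeric matrix.
#' @export
spectral_transform <- function(D, kind = c("pca", "laplacian"), d) {
  kind <- match.arg(kind)
  n <- nrow(D)
  d <- check_count(d, "d")
  if (d > n) stopf("embedding dimension d=%d exceeds n=%d", d, n)
  if (max(D) - min(D) == 0)
    stopf("degenerate distance matrix (all entries equal): rank-deficient")
  if (kind == "pca") {
    pc <- stats::prcomp(D, center = TRUE, scale. = FALSE)
    emb <- pc$x[, seq_len(d), drop = FALSE]
  } else {
    S <- exp(-D / max(D))
    deg <- rowSums(S)
    inv_sqrt <- 1 / sqrt(deg)
    L <- diag(n) - (inv_sqrt %o% inv_sqrt) * S
    eig <- eigen(L, symmetric = TRUE)
    # eigen() sorts decreasing; reorder so column 1 has the smallest eigenvalue
    emb <- eig$vectors[, seq(n, n - d + 1L), drop = FALSE]
  }
  rownames(emb) <- rownames(D)
  emb
}

kmeanspp_centers <- function(X, k, seed) {
  withr::with_seed(seed, {
    n <- nrow(X)
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    d2 <- rowSums((X - rep(X[centers[1L], ], each = n))^2)
    for (i in seq_len(k - 1L)) {
      if (all(d2 == 0)) {
        centers[i + 1L] <- sample.int(n, 1L)
      } else {
        centers[i + 1L] <- sample.int(n, 1L, prob = d2)
      }
      di <- rowSums((X - rep(X[centers[i + 1L], ], each = n))^2)
      d2 <- pmin(d2, di)
    }
    centers
  })
}

kmeans_once <- function(X, k, seed, nstart = 10L, iter_max = 300L) {
  best <- NULL
  for (restart in seq_len(nstart)) {
    ctr_idx <- kmeanspp_centers(X, k, stable_seed(seed, "restart", restart))
    ctrs <- X[ctr_idx, , drop = FALSE]
    fit <- tryCatch(
      withr::with_seed(stable_seed(seed, "km", restart),
                       stats::kmeans(X, centers = ctrs, iter.max = iter_max)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best)) {
    # degenerate geometry (e.g. fewer distinct points than k): fall back to a
    # hierarchical cut, which always yields k groups
    hc <- stats::hclust(stats::dist(X), method = "complete")
    return(stats::cutree(hc, k = k))
  }
  best$cluster
}

#' k-means ensemble over the SC3 parameter grid
#'
#' Runs k-means (k-means++ initialization, 10 restarts, 300 iterations) on
#' every combination of distance metric (euclidean, pearson, spearman),
#' spectral transform (pca, laplacian) and embedding dimension
#' `d in round(d_range * n)` — the SC3 default grid of 4–7% of the cell
#' number. Per-grid-point seeds are derived deterministically from `seed`.
#'
#' @param P a `PreprocessedMatrix`.
#' @param k number of clusters (>= 2, < n).
#' @param d_range fraction interval for the embedding dimensions; default
#'   `c(0.04, 0.07)`.
#' @param seed master seed for the ensemble.
#' @param metrics,kinds grid axes; defaults are the full SC3 grid.
#' @return list of [ClusterLabels], one per grid point.
#' @export
kmeans_ensemble <- function(P, k, d_range = c(0.04, 0.07), seed = 1L,
                            metrics = c("euclidean", "pearson", "spearman"),
                            kinds = c("pca", "laplacian")) {
  stopifnot(inherits(P, "PreprocessedMatrix"))
  k <- check_count(k, "k", min = 2L)
  n <- ncol(P$values)
  if (n <= k) stopf("need more cells (%d) than clusters (%d)", n, k)

  ds <- seq(round(d_range[1] * n), round(d_range[2] * n))
  ds <- ds[ds >= 2L & ds <= n - 1L]
  if (length(ds) == 0L) {
    ds <- min(n - 1L, k + 1L)
    warnf("d_range [%g, %g] gives no usable dimension at n=%d; using d=%d",
          d_range[1], d_range[2], n, ds)
  }
  d_max <- max(ds)

  ensemble <- list()
  for (metric in metrics) {
    D <- cell_distances(P, metric)
    for (kind in kinds) {
      emb_full <- spectral_transform(D, kind, d_max)
      for (d in ds) {
        cl <- kmeans_once(emb_full[, seq_len(d), drop = FALSE], k,
                          stable_seed(seed, metric, kind, d))
        ensemble[[length(ensemble) + 1L]] <- ClusterLabels(cl, k)
      }
    }
  }
  ensemble
}

#' Consensus matrix from a clustering ensemble
#'
#' `c_ij` is the fraction of labelings in which cells i and j share a
#' cluster; the diagonal is 1 by definition.
#'
#' @param ensemble non-empty list of [ClusterLabels] over the same cells.
#' @param cell_ids optional cell identifiers for the result.
#' @return a [ConsensusMatrix].
#' @export
consensus_from_ensemble <- function(ensemble, cell_ids = NULL) {
  if (length(ensemble) == 0L) stopf("empty ensemble")
  ns <- vapply(ensemble, function(t) length(t$labels), integer(1))
  if (length(unique(ns)) != 1L)
    stopf("labelings cover different cell counts: %s",
          paste(unique(ns), collapse = ", "))
  n <- ns[1L]
  acc <- matrix(0, n, n)
  for (t in ensemble) {
    # indicator of co-membership via cluster membership matrix
    Z <- outer(t$labels, t$labels, "==")
    acc <- acc + Z
  }
  acc <- acc / length(ensemble)
  diag(acc) <- 1
  ConsensusMatrix(acc, cell_ids = cell_ids)
}

#' Final clustering of the consensus matrix
#'
#' Hierarchical clustering with complete linkage on the distance
#' `1 - c_ij`, cut into `k` clusters; labels are renumbered to consecutive
#' `1..k` by order of first appearance.
#'
#' @param C a [ConsensusMatrix].
#' @param k number of clusters (2..n).
#' @return a [ClusterLabels].
#' @export
cluster_consensus <- function(C, k) {
  stopifnot(inherits(C, "ConsensusMatrix"))
  n <- nrow(C$values)
  k <- check_count(k, "k", min = 1L)
  if (k > n) stopf("k=%d exceeds number of cells n=%d", k, n)
  hc <- stats::hclust(stats::as.dist(1 - C$values), method = "complete")
  cl <- stats::cutree(hc, k = k)
  relabeled <- match(cl, unique(cl))
  ClusterLabels(relabeled, k)
}

#' One full consensus-clustering pass
#'
#' Convenience wrapper chaining [filter_genes()], [kmeans_ensemble()],
#' [consensus_from_ensemble()] and [cluster_consensus()] — the unit the
#' selection driver repeats per preprocessing method.
#'
#' @param P a `PreprocessedMatrix`.
#' @param k number of clusters.
#' @param seed ensemble seed.
#' @param d_range embedding-dimension fractions, see [kmeans_ensemble()].
#' @param filter apply the SC3 gene filter first?
#' @param lower_pct,upper_pct gene-filter bounds.
#' @return list with elements `consensus` ([ConsensusMatrix]) and `labels`
#'   ([ClusterLabels]).
#' @export
sc3_consensus <- function(P, k, seed = 1L, d_range = c(0.04, 0.07),
                          filter = TRUE, lower_pct = 0.06, upper_pct = 0.94) {
  if (filter) P <- filter_genes(P, lower_pct, upper_pct)
  ens <- kmeans_ensemble(P, k, d_range = d_range, seed = seed)
  C <- consensus_from_ensemble(ens, cell_ids = colnames(P$values))
  T_ <- cluster_consensus(C, k)
  list(consensus = C, labels = T_)
}
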
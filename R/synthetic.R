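#' Configuration for the clustered scRNA-seq count simulator
#'
#' The generator emulates the features of real single-cell expression data
#' the pipeline is sensitive to: negative-binomial counts with a mean-
#' dispersion parameterization (variance `mu + dispersion * mu^2`),
#' cluster-specific fold changes on a random subset of genes, extra
#' zero-inflation (dropout), per-cell library-size variation, and output in
#' any of the unit conventions found in published data sets (READS, CPM,
#' TPM, RPKM, FPKM, QN), with gene lengths drawn for the per-kilobase units.
#'
#' Defaults describe a small, clearly clustered data set: 90 cells, 2000
#' genes, 3 equally sized clusters, 10% of genes differentially expressed
#' per cluster at 2-fold (log2 fold change 1), NB dispersion 0.1, 10%
#' dropout, 20% library-size CV — sizes a desk-scale test can cluster in
#' seconds while still exercising every pipeline stage.
#'
#' @param n_cells,n_genes,k_clusters dimensions of the simulation.
#' @param de_fraction fraction of genes differentially expressed in each
#'   cluster.
#' @param log2_fold_change effect size; each cluster's DE genes are scaled
#'   by `2^(+/- log2_fold_change)` (sign random per gene).
#' @param dispersion NB dispersion; variance is `mu + dispersion * mu^2`.
#' @param dropout_rate probability of zeroing any count, on top of NB zeros.
#' @param library_size_cv coefficient of variation of per-cell library-size
#'   factors (log-normal).
#' @param units_out output units; counts are converted after simulation.
#' @param gene_length_range gene lengths (bp) drawn uniformly for RPKM/FPKM
#'   and TPM conversion.
#' @param mean_log,sd_log log-normal baseline for gene mean expression.
#' @param seed integer seed; the same config reproduces identical fixtures.
#' @return an object of class `SimConfig`.
#' @export
SimConfig <- function(n_cells = 90L, n_genes = 2000L, k_clusters = 3L,
                      de_fraction = 0.1, log2_fold_change = 1,
                      dispersion = 0.1, dropout_rate = 0.1,
                      library_size_cv = 0.2, units_out = "READS",
                      gene_length_range = c(500, 5000),
                      mean_log = 1, sd_log = 1, seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells")
  n_genes <- check_count(n_genes, "n_genes")
  k_clusters <- check_count(k_clusters, "k_clusters")
  if (k_clusters > n_cells) stopf("k_clusters exceeds n_cells")
  check_fraction(de_fraction, "de_fraction")
  check_fraction(dropout_rate, "dropout_rate")
  check_scalar(log2_fold_change, "log2_fold_change",
               function(v) is.numeric(v) && v >= 0, "nonnegative number")
  check_scalar(dispersion, "dispersion",
               function(v) is.numeric(v) && v >= 0, "nonnegative number")
  check_scalar(library_size_cv, "library_size_cv",
               function(v) is.numeric(v) && v >= 0, "nonnegative number")
  units_out <- match.arg(units_out, setdiff(EXPRESSION_UNITS, "UNKNOWN"))
  if (length(gene_length_range) != 2L || any(gene_length_range <= 0) ||
      gene_length_range[1] > gene_length_range[2])
    stopf("gene_length_range must be a positive increasing interval")
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 k_clusters = k_clusters, de_fraction = de_fraction,
                 log2_fold_change = log2_fold_change,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 library_size_cv = library_size_cv, units_out = units_out,
                 gene_length_range = gene_length_range,
                 mean_log = mean_log, sd_log = sd_log,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

convert_units <- function(counts, units, lengths_bp) {
  libsize <- colSums(counts)
  scale_cols <- function(x, denom) {
    denom[denom == 0] <- 1          # all-zero cells stay all-zero
    sweep(x, 2L, denom, "/")
  }
  switch(units,
    READS = counts,
    CPM = scale_cols(counts, libsize) * 1e6,
    TPM = {
      rate <- counts / (lengths_bp / 1000)
      scale_cols(rate, colSums(rate)) * 1e6
    },
    RPKM = ,
    FPKM = scale_cols(counts / (lengths_bp / 1000), libsize) * 1e6,
    QN = limma::normalizeQuantiles(counts))
}

#' Simulate clustered scRNA-seq counts with known labels
#'
#' Baseline per-gene means are log-normal; each cluster scales its own DE
#' gene subset by `2^(+/- log2_fold_change)`; counts are negative binomial
#' with per-cell library-size factors; dropout zeros are injected; and the
#' count matrix is finally converted to the requested units. Planted labels
#' are returned alongside the matrix so downstream accuracy is measurable.
#'
#' @param config a [SimConfig].
#' @return list with `matrix` (an [ExpressionMatrix]), `labels` (a
#'   [ClusterLabels]), `gene_lengths` (bp) and `de_genes` (k-column logical
#'   matrix of per-cluster DE memberships).
#' @export
simulate_counts <- function(config = SimConfig()) {
  stopifnot(inherits(config, "SimConfig"))
  withr::with_seed(config$seed, {
    m <- config$n_genes
    n <- config$n_cells
    k <- config$k_clusters

    base_mean <- stats::rlnorm(m, meanlog = config$mean_log,
                               sdlog = config$sd_log)
    lengths_bp <- round(stats::runif(m, config$gene_length_range[1],
                                     config$gene_length_range[2]))

    labels <- rep(seq_len(k), length.out = n)
    de <- matrix(FALSE, m, k)
    fold <- matrix(1, m, k)
    for (cl in seq_len(k)) {
      de_idx <- sample.int(m, round(config$de_fraction * m))
      de[de_idx, cl] <- TRUE
      sign <- sample(c(-1, 1), length(de_idx), replace = TRUE)
      fold[de_idx, cl] <- 2^(sign * config$log2_fold_change)
    }

    sf <- if (config$library_size_cv > 0) {
      sdl <- sqrt(log(1 + config$library_size_cv^2))
      stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
    } else rep(1, n)

    mu <- fold[, labels, drop = FALSE] * base_mean
    mu <- sweep(mu, 2L, sf, "*")
    counts <- matrix(
      if (config$dispersion > 0)
        stats::rnbinom(m * n, mu = mu, size = 1 / config$dispersion)
      else
        stats::rpois(m * n, lambda = mu),
      m, n)

    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(m * n) < config$dropout_rate, m, n)
      counts[drop] <- 0
    }

    values <- convert_units(counts, config$units_out, lengths_bp)
    M <- ExpressionMatrix(values, units = config$units_out)
    list(matrix = M,
         labels = ClusterLabels(labels, k),
         gene_lengths = lengths_bp,
         de_genes = de)
  })
}

#' Simulate a planted-block consensus matrix
#'
#' Direct fixture for graph scoring: a block matrix with `within_mean` on
#' same-cluster pairs and `between_mean` elsewhere, plus Gaussian noise on
#' the off-diagonal entries, truncated to \[0, 1\], symmetrized, unit
#' diagonal.
#'
#' @param n_cells number of cells.
#' @param k number of planted clusters.
#' @param within_mean,between_mean block means, `0 <= between <= within <= 1`.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param seed integer seed.
#' @return list with `consensus` (a [ConsensusMatrix]) and `labels` (a
#'   [ClusterLabels]).
#' @export
simulate_consensus <- function(n_cells, k, within_mean = 0.9,
                               between_mean = 0.1, noise_sd = 0.05,
                               seed = 1L) {
  n_cells <- check_count(n_cells, "n_cells", min = 2L)
  k <- check_count(k, "k")
  if (k > n_cells) stopf("k exceeds n_cells")
  check_fraction(within_mean, "within_mean")
  check_fraction(between_mean, "between_mean")
  if (between_mean > within_mean)
    stopf("need between_mean <= within_mean")
  withr::with_seed(seed, {
    labels <- rep(seq_len(k), length.out = n_cells)
    C <- ifelse(outer(labels, labels, "=="), within_mean, between_mean)
    if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(n_cells^2, sd = noise_sd), n_cells)
      noise <- (noise + t(noise)) / 2
      C <- C + noise
    }
    C <- pmin(pmax(C, 0), 1)
    diag(C) <- 1
    list(consensus = ConsensusMatrix(C),
         labels = ClusterLabels(labels, k))
  })
}
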
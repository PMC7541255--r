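test_that("gene filter keeps exactly the genes inside the detection band", {
  # 5 genes x 10 cells with detection counts 0, 2, 5, 9, 10
  det <- c(0, 2, 5, 9, 10)
  v <- t(vapply(det, function(d) c(rep(1, d), rep(0, 10 - d)), numeric(10)))
  M <- ExpressionMatrix(v)
  P <- no_transform(M)
  # lower 0.06*10 = 0.6, upper 0.94*10 = 9.4: keep detection in {2, 5, 9}
  F1 <- filter_genes(P, 0.06, 0.94)
  expect_identical(rownames(F1$values), gene_ids(M)[det %in% c(2, 5, 9)])
  # upper_pct = 1: a gene detected in every cell is kept (boundary not strict)
  F2 <- filter_genes(P, 0.06, 1)
  expect_true(gene_ids(M)[5] %in% rownames(F2$values))
  # gene detected in 0 cells always removed for lower_pct > 0
  expect_false(gene_ids(M)[1] %in% rownames(F2$values))
  # band [9.5, 9.9] contains none of the detection counts
  expect_error(filter_genes(P, 0.95, 0.99), "every gene")
})

test_that("gene filter uses detection on the untransformed scale", {
  M <- ExpressionMatrix(rbind(c(5, 5, 5, 5), c(0, 0, 0, 4)))
  Pz <- zscore_transform(M)       # z-scores are nonzero where raw was zero
  Fz <- filter_genes(Pz, 0.3, 1)  # needs detection >= 1.2 cells
  expect_identical(rownames(Fz$values), gene_ids(M)[1])
})

test_that("cell distances match hand-computed cases", {
  # euclidean 3-4-5 triangle
  Me <- no_transform(ExpressionMatrix(cbind(c(0, 0), c(3, 4))))
  De <- cell_distances(Me, "euclidean")
  expect_equal(De[1, 2], 5)
  # pearson distance 2 for perfectly anticorrelated columns
  Mp <- no_transform(ExpressionMatrix(cbind(c(1, 2, 3), c(3, 2, 1))))
  expect_equal(cell_distances(Mp, "pearson")[1, 2], 2)
  expect_equal(cell_distances(Mp, "spearman")[1, 2], 2)
  # identical columns: distance 0 under all metrics
  Mi <- no_transform(ExpressionMatrix(cbind(c(1, 5, 2), c(1, 5, 2))))
  for (m in c("euclidean", "pearson", "spearman"))
    expect_equal(cell_distances(Mi, m)[1, 2], 0, label = m)
})

test_that("distance matrices are symmetric, zero-diagonal; constant cells get distance 1", {
  withr::with_seed(3, {
    M <- no_transform(ExpressionMatrix(matrix(rpois(20 * 8, 5), 20)))
    for (metric in c("euclidean", "pearson", "spearman")) {
      D <- cell_distances(M, metric)
      expect_equal(D, t(D), label = metric)
      expect_equal(unname(diag(D)), rep(0, 8))
    }
  })
  Mz <- no_transform(ExpressionMatrix(cbind(c(0, 0, 0), c(1, 2, 3), c(5, 1, 2))))
  for (metric in c("pearson", "spearman")) {
    D <- cell_distances(Mz, metric)
    expect_equal(unname(D[1, 2:3]), c(1, 1), label = metric)
    expect_equal(D[1, 1], 0)
  }
})

test_that("spectral embeddings have the right shape and PCA columns are orthogonal", {
  withr::with_seed(7, {
    M <- no_transform(ExpressionMatrix(matrix(rpois(30 * 12, 5), 30)))
    D <- cell_distances(M, "euclidean")
    for (kind in c("pca", "laplacian")) {
      E <- spectral_transform(D, kind, 4)
      expect_identical(dim(E), c(12L, 4L), label = kind)
    }
    E <- spectral_transform(D, "pca", 4)
    G <- crossprod(E)
    expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  })
  expect_error(spectral_transform(matrix(0, 4, 4), "pca", 2), "degenerate")
})

test_that("the Fiedler coordinate of the Laplacian splits a two-blob distance matrix", {
  # 6 cells: blobs {1,2,3} and {4,5,6}, near 0 within, near 1 between
  blob <- rep(1:2, each = 3)
  D <- ifelse(outer(blob, blob, "=="), 0.05, 1)
  diag(D) <- 0
  E <- spectral_transform(D, "laplacian", 3)

  # independent oracle: brute-force eigendecomposition of the same Laplacian
  S <- exp(-D / max(D))
  L <- diag(6) - diag(1 / sqrt(rowSums(S))) %*% S %*% diag(1 / sqrt(rowSums(S)))
  ev <- eigen(L, symmetric = TRUE)
  fiedler <- ev$vectors[, 5]   # second-smallest eigenvalue
  expect_equal(length(unique(sign(fiedler[1:3]))), 1)
  expect_true(all(sign(fiedler[4:6]) == -sign(fiedler[1])))

  # implementation's column 2 (ascending eigenvalue) matches up to sign
  expect_equal(abs(E[, 2]), abs(fiedler), tolerance = 1e-10)
  expect_equal(length(unique(sign(E[1:3, 2]))), 1)
  expect_true(all(sign(E[4:6, 2]) == -sign(E[1, 2])))
})

test_that("the k-means ensemble covers the full grid deterministically", {
  withr::with_seed(13, {
    M <- no_transform(ExpressionMatrix(matrix(rpois(20 * 100, 5) + 1, 20)))
    ens <- kmeans_ensemble(M, k = 3, seed = 99)
    # n = 100: d in {4,...,7}; 3 metrics x 2 transforms x 4 d = 24 labelings
    expect_length(ens, 24)
    for (t in ens) {
      expect_s3_class(t, "ClusterLabels")
      expect_lte(length(unique(t$labels)), 3)
    }
    ens2 <- kmeans_ensemble(M, k = 3, seed = 99)
    expect_identical(ens, ens2)
    ens3 <- kmeans_ensemble(M, k = 3, seed = 100)
    expect_false(identical(ens, ens3))
  })
})

test_that("an unusable d_range falls back with a warning", {
  withr::with_seed(17, {
    M <- no_transform(ExpressionMatrix(matrix(rpois(10 * 8, 5) + 1, 10)))
    expect_warning(ens <- kmeans_ensemble(M, k = 2, d_range = c(0.01, 0.02),
                                          seed = 1),
                   "d_range")
    expect_length(ens, 6)  # one d, 3 metrics x 2 transforms
  })
})

test_that("consensus matrix is the exact co-clustering fraction", {
  ens <- list(ClusterLabels(c(1, 1, 2), 2), ClusterLabels(c(1, 2, 2), 2))
  C <- consensus_from_ensemble(ens)
  expect_equal(C$values[1, 2], 0.5)
  expect_equal(C$values[1, 3], 0)
  expect_equal(C$values[2, 3], 0.5)
  expect_equal(unname(diag(C$values)), rep(1, 3))
  expect_equal(C$values, t(C$values))

  # unanimity: identical labelings give a 0/1 block matrix
  uni <- consensus_from_ensemble(list(ClusterLabels(c(1, 2, 1), 2),
                                      ClusterLabels(c(2, 1, 2), 2)))
  expect_true(all(uni$values %in% c(0, 1)))
  expect_error(consensus_from_ensemble(list(ClusterLabels(1:2, 2),
                                            ClusterLabels(1:3, 3))),
               "different cell counts")
})

test_that("consensus entries times ensemble size are integers", {
  withr::with_seed(19, {
    for (rep_i in 1:5) {
      ens <- lapply(1:7, function(i)
        ClusterLabels(sample.int(3, 15, replace = TRUE), 3))
      C <- consensus_from_ensemble(ens)
      expect_equal(C$values[upper.tri(C$values)] * 7,
                   round(C$values[upper.tri(C$values)] * 7))
    }
  })
})

test_that("cluster_consensus recovers blocks and renumbers by first appearance", {
  labels <- rep(c(2, 1), each = 4)  # planted, deliberately not 1-first
  Cv <- ifelse(outer(labels, labels, "=="), 1, 0)
  diag(Cv) <- 1
  T_ <- cluster_consensus(ConsensusMatrix(Cv), 2)
  expect_identical(T_$labels, rep(c(1L, 2L), each = 4))

  # k = n: every cell its own cluster
  Tn <- cluster_consensus(ConsensusMatrix(diag(4)), 4)
  expect_identical(Tn$labels, 1:4)
  expect_error(cluster_consensus(ConsensusMatrix(diag(4)), 5), "exceeds")

  # noisy blocks, n = 20: exact recovery
  sim <- simulate_consensus(20, 2, within_mean = 0.9, between_mean = 0.1,
                            noise_sd = 0.05, seed = 4)
  Tr <- cluster_consensus(sim$consensus, 2)
  expect_equal(adjusted_rand_index(Tr, sim$labels), 1)
})

test_that("the pipeline recovers well-separated planted clusters across seeds", {
  for (s in 1:3) {
    sim <- simulate_counts(SimConfig(n_cells = 60, n_genes = 300,
                                     k_clusters = 3, log2_fold_change = 2,
                                     de_fraction = 0.2, seed = s))
    run <- sc3_consensus(log_transform(sim$matrix), k = 3, seed = s)
    expect_gte(adjusted_rand_index(run$labels, sim$labels), 0.9)
  }
})

test_that("consensus TSV round trip is exact", {
  sim <- simulate_consensus(12, 3, seed = 8)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "c.tsv")
  write_consensus(sim$consensus, p)
  back <- read_consensus(p)
  expect_identical(back$values, sim$consensus$values)
})
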
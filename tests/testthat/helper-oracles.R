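# Brute-force oracles, deliberately written as verbatim loops over the
# defining formulas and kept independent of the implementation paths they
# check.

# C-score oracle: enumerate every unordered cell pair, apply the edge rules
# and the three contraction formulas literally.
oracle_c_score <- function(Cv, labels, alpha, beta) {
  n <- nrow(Cv)
  clusters <- sort(unique(labels))
  in_w <- lapply(clusters, function(x) numeric(0))
  names(in_w) <- as.character(clusters)
  out_w <- list()  # keyed "a|b", a < b
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      cij <- Cv[i, j]
      if (labels[i] == labels[j]) {
        if (cij < alpha) {
          key <- as.character(labels[i])
          in_w[[key]] <- c(in_w[[key]], cij)
        }
      } else if (cij > beta) {
        key <- paste(min(labels[i], labels[j]), max(labels[i], labels[j]),
                     sep = "|")
        out_w[[key]] <- c(out_w[[key]], cij)
      }
    }
  }
  w <- vapply(as.character(clusters), function(m) {
    e <- in_w[[m]]
    if (length(e) == 0) 0 else sum(alpha - e) / length(e)
  }, numeric(1))
  d_pair <- vapply(out_w, function(e) sum(e - beta) / length(e), numeric(1))
  d <- vapply(clusters, function(m) {
    tot <- 0
    for (key in names(out_w)) {
      ab <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
      if (m %in% ab) tot <- tot + d_pair[[key]]
    }
    tot
  }, numeric(1))
  nn <- length(clusters)
  W_in <- sum(w) / nn
  D_out <- sum(d) / nn
  list(W_in = W_in, D_out = D_out, c_score = W_in * D_out)
}

# ARI oracle via pair counting (a different route than the contingency-table
# formula): classify all unordered pairs as together/apart in each partition.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) {
    same <- identical(match(a, unique(a)), match(b, unique(b)))
    return(if (same) 1 else 0)
  }
  2 * (n11 * n00 - n10 * n01) / denom
}

# random valid (consensus, labels) instance for property tests
random_instance <- function(seed, n_max = 20L) {
  withr::with_seed(seed, {
    n <- sample(4:n_max, 1)
    k <- sample(2:min(4, n - 1), 1)
    labels <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
    Cv <- matrix(runif(n * n), n)
    Cv <- (Cv + t(Cv)) / 2
    diag(Cv) <- 1
    list(C = ConsensusMatrix(Cv), labels = ClusterLabels(labels, k),
         alpha = runif(1), beta = runif(1))
  })
}

# small fixed expression matrix used across IO and preprocessing tests
tiny_expression <- function() {
  ExpressionMatrix(matrix(c(0, 3, 7,
                            2, 4, 6), nrow = 3),
                   gene_ids = c("g1", "g2", "g3"),
                   cell_ids = c("c1", "c2"),
                   units = "READS")
}

# the worked 4-cell, 2-cluster micro-instance used in the graph-score tests
micro_instance <- function() {
  Cv <- diag(4)
  Cv[1, 2] <- Cv[2, 1] <- 0.4
  Cv[3, 4] <- Cv[4, 3] <- 0.7
  Cv[1, 3] <- Cv[3, 1] <- 0.6
  Cv[1, 4] <- Cv[4, 1] <- 0.3
  Cv[2, 3] <- Cv[3, 2] <- 0.3
  Cv[2, 4] <- Cv[4, 2] <- 0.3
  list(C = ConsensusMatrix(Cv), labels = ClusterLabels(c(1, 1, 2, 2), 2))
}

# planted data set where z-score is ARI-best by a wide margin: one
# huge-magnitude gene, uncorrelated with the clusters, swamps raw Euclidean
# and Pearson distances; z-scoring tames it.
dominated_gene_input <- function(seed, n_cells = 60L, n_genes = 300L) {
  sim <- simulate_counts(SimConfig(n_cells = n_cells, n_genes = n_genes,
                                   k_clusters = 3L, log2_fold_change = 1.5,
                                   de_fraction = 0.15, seed = seed))
  v <- sim$matrix$values
  huge <- withr::with_seed(seed + 1000L, {
    h <- stats::runif(ncol(v), 1e5, 1e6)
    # zero out 10% of cells so the gene stays below the 94% detection cap
    h[sample.int(ncol(v), ceiling(0.1 * ncol(v)))] <- 0
    h
  })
  v[1, ] <- huge
  list(M = ExpressionMatrix(v, units = "READS"), truth = sim$labels)
}

# degrade a labeling by randomly reassigning a fraction of labels
degrade_labels <- function(T_, frac, seed) {
  l <- T_$labels
  withr::with_seed(seed, {
    nflip <- round(frac * length(l))
    if (nflip > 0) {
      idx <- sample.int(length(l), nflip)
      l[idx] <- sample.int(T_$num_clusters, nflip, replace = TRUE)
    }
  })
  ClusterLabels(l, T_$num_clusters)
}
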
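test_that("the worked 4-cell instance yields the hand-derived edges and scores", {
  mi <- micro_instance()
  G <- build_clustering_graph(mi$C, mi$labels, GraphParams(0.6, 0.5))

  # one in-cluster edge (1,2,0.4) in cluster 1; pair (3,4) has 0.7 >= alpha
  expect_equal(nrow(G$in_edges), 1)
  expect_equal(G$in_edges$i, 1)
  expect_equal(G$in_edges$j, 2)
  expect_equal(G$in_edges$weight, 0.4)
  expect_equal(G$in_edges$cluster, 1)
  # one out-cluster edge (1,3,0.6); all other cross pairs are 0.3 <= beta
  expect_equal(nrow(G$out_edges), 1)
  expect_equal(G$out_edges[1, c("i", "j", "weight")],
               data.frame(i = 1L, j = 3L, weight = 0.6), ignore_attr = TRUE)

  CG <- contract_graph(G)
  nodes <- CG$nodes[order(CG$nodes$cluster), ]
  expect_equal(nodes$w, c((0.6 - 0.4) / 1, 0))        # w_A = 0.2, w_B = 0
  expect_equal(CG$edges$d_ij, (0.6 - 0.5) / 1)        # d_AB = 0.1
  expect_equal(nodes$d, c(0.1, 0.1))

  cs <- c_score(CG)
  expect_equal(cs$W_in, 0.1)
  expect_equal(cs$D_out, 0.1)
  expect_equal(cs$c_score, 0.01)
  expect_false(cs$zero_score)
})

test_that("ideal consensus gives empty graphs and a flagged zero score", {
  labels <- rep(1:3, each = 4)
  Cv <- ifelse(outer(labels, labels, "=="), 1, 0)
  diag(Cv) <- 1
  G <- build_clustering_graph(ConsensusMatrix(Cv), ClusterLabels(labels, 3),
                              GraphParams())
  expect_equal(nrow(G$in_edges), 0)
  expect_equal(nrow(G$out_edges), 0)
  CG <- contract_graph(G)
  expect_equal(nrow(CG$nodes), 3)   # isolated cluster nodes still appear
  expect_equal(CG$nodes$w, rep(0, 3))
  expect_equal(CG$nodes$d, rep(0, 3))
  cs <- c_score(CG)
  expect_equal(cs$c_score, 0)
  expect_true(cs$zero_score)
})

test_that("alpha = 0 admits no in-cluster edges; beta thresholds are strict", {
  mi <- micro_instance()
  G0 <- build_clustering_graph(mi$C, mi$labels, GraphParams(alpha = 0, beta = 0.5))
  expect_equal(nrow(G0$in_edges), 0)
  # a pair exactly at beta adds no edge
  Gb <- build_clustering_graph(mi$C, mi$labels, GraphParams(0.6, beta = 0.6))
  expect_equal(nrow(Gb$out_edges), 0)
  # a pair exactly at alpha adds no edge (c_34 = 0.7)
  Ga <- build_clustering_graph(mi$C, mi$labels, GraphParams(alpha = 0.7, beta = 0.5))
  expect_false(any(Ga$in_edges$i == 3 & Ga$in_edges$j == 4))
})

test_that("multiple out-cluster edges between two clusters are averaged", {
  labels <- c(1, 1, 2, 2)
  Cv <- diag(4)
  Cv[1, 3] <- Cv[3, 1] <- 0.7
  Cv[2, 4] <- Cv[4, 2] <- 0.9
  CG <- contract_graph(build_clustering_graph(ConsensusMatrix(Cv),
                                              ClusterLabels(labels, 2),
                                              GraphParams(0.6, 0.5)))
  expect_equal(CG$edges$d_ij, ((0.7 - 0.5) + (0.9 - 0.5)) / 2)  # 0.3
  expect_equal(CG$edges$n_edges, 2)
})

test_that("dimension mismatch is rejected", {
  mi <- micro_instance()
  expect_error(build_clustering_graph(mi$C, ClusterLabels(c(1, 1, 2), 2),
                                      GraphParams()),
               "4 cells")
})

test_that("implementation agrees with the brute-force oracle on random instances", {
  for (s in 1:60) {
    inst <- random_instance(s)
    got <- consensus_c_score(inst$C, inst$labels,
                             GraphParams(inst$alpha, inst$beta))
    want <- oracle_c_score(inst$C$values, inst$labels$labels,
                           inst$alpha, inst$beta)
    expect_equal(got$W_in, want$W_in, tolerance = 1e-12)
    expect_equal(got$D_out, want$D_out, tolerance = 1e-12)
    expect_equal(got$c_score, want$c_score, tolerance = 1e-12)
  }
})

test_that("the C-score is invariant under cluster relabeling", {
  for (s in 1:10) {
    inst <- random_instance(s + 500)
    perm <- withr::with_seed(s, sample.int(inst$labels$num_clusters))
    relab <- ClusterLabels(perm[inst$labels$labels], inst$labels$num_clusters)
    a <- consensus_c_score(inst$C, inst$labels, GraphParams(inst$alpha, inst$beta))
    b <- consensus_c_score(inst$C, relab, GraphParams(inst$alpha, inst$beta))
    expect_equal(a$c_score, b$c_score, tolerance = 1e-12)
  }
})

test_that("edge sets and exceedance sums respond monotonically to alpha and beta", {
  # Note the averaged scores W_in and D_out themselves are NOT monotone in
  # the thresholds: each w_i and d_ij is an average, and a new edge entering
  # (or a weak edge leaving) changes the denominator as well as the
  # numerator. What is monotone: the edge sets grow with alpha / shrink
  # with beta, and so do the raw exceedance sums sum(alpha - c) and
  # sum(r - beta) before averaging.
  grid <- seq(0, 1, by = 0.1)
  for (s in 1:10) {
    inst <- random_instance(s + 900)
    n_in <- sum_in <- n_out <- sum_out <- numeric(length(grid))
    for (gi in seq_along(grid)) {
      Ga <- build_clustering_graph(inst$C, inst$labels,
                                   GraphParams(grid[gi], 0.5))
      n_in[gi] <- nrow(Ga$in_edges)
      sum_in[gi] <- sum(grid[gi] - Ga$in_edges$weight)
      Gb <- build_clustering_graph(inst$C, inst$labels,
                                   GraphParams(0.6, grid[gi]))
      n_out[gi] <- nrow(Gb$out_edges)
      sum_out[gi] <- sum(Gb$out_edges$weight - grid[gi])
    }
    expect_true(all(diff(n_in) >= 0), label = sprintf("in-edge count seed %d", s))
    expect_true(all(diff(sum_in) >= -1e-12))
    expect_true(all(diff(n_out) <= 0), label = sprintf("out-edge count seed %d", s))
    expect_true(all(diff(sum_out) <= 1e-12))
  }
})

test_that("graph exports are readable TSV edge lists", {
  mi <- micro_instance()
  G <- build_clustering_graph(mi$C, mi$labels, GraphParams())
  dir <- withr::local_tempdir()
  p <- file.path(dir, "graph.tsv")
  write_graph(G, p, cell_ids = mi$C$cell_ids)
  df <- read.delim(p)
  expect_identical(sort(unique(df$type)), c("in", "out"))
  expect_equal(nrow(df), 2)
  write_graph(contract_graph(G), file.path(dir, "cg"))
  nodes <- read.delim(file.path(dir, "cg_nodes.tsv"))
  expect_identical(names(nodes), c("cluster", "w", "d", "k"))
})
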
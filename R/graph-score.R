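#' Thresholds for the clustering graph
#'
#' `alpha` bounds in-cluster edges: an edge flags a same-cluster cell pair
#' whose consensus value falls strictly below `alpha` (weak within-cluster
#' support). `beta` bounds out-cluster edges: an edge flags a
#' different-cluster pair whose consensus value lies strictly above `beta`
#' (leakage between clusters). Ties at exactly `alpha` or `beta` add no
#' edge. Lowering `alpha` removes in-cluster edges; raising `beta` removes
#' out-cluster edges; pushed too far, both edge sets empty out and the
#' C-score degenerates to 0 for every method (see the `zero_score` flag).
#'
#' @param alpha in-cluster threshold in \[0, 1\], default 0.6.
#' @param beta out-cluster threshold in \[0, 1\], default 0.5.
#' @return an object of class `GraphParams`.
#' @export
GraphParams <- function(alpha = 0.6, beta = 0.5) {
  check_fraction(alpha, "alpha")
  check_fraction(beta, "beta")
  structure(list(alpha = alpha, beta = beta), class = "GraphParams")
}

#' Build the clustering graph from a consensus matrix and a clustering
#'
#' Nodes are cells. For every unordered cell pair (i, j):
#' same cluster and `c_ij < alpha` adds an in-cluster edge of weight `c_ij`;
#' different clusters and `c_ij > beta` adds an out-cluster edge of weight
#' `c_ij`; otherwise no edge. Both comparisons are strict.
#'
#' @param C a [ConsensusMatrix].
#' @param T_ a [ClusterLabels] over the same cells.
#' @param params a [GraphParams].
#' @return an object of class `ClusteringGraph`: list with `n_cells`,
#'   `clusters` (sorted ids occupied in `T_`), `in_edges` (data.frame
#'   `i, j, weight, cluster`) and `out_edges` (data.frame
#'   `i, j, weight, cluster_a, cluster_b`, with `cluster_a < cluster_b`).
#' @export
build_clustering_graph <- function(C, T_, params = GraphParams()) {
  stopifnot(inherits(C, "ConsensusMatrix"), inherits(T_, "ClusterLabels"),
            inherits(params, "GraphParams"))
  n <- nrow(C$values)
  if (length(T_$labels) != n)
    stopf("consensus matrix has %d cells but labeling has %d",
          n, length(T_$labels))
  lab <- T_$labels
  cv <- C$values

  idx <- which(upper.tri(cv), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  w <- cv[idx]
  same <- lab[i] == lab[j]

  in_sel <- same & w < params$alpha
  out_sel <- !same & w > params$beta

  in_edges <- data.frame(i = i[in_sel], j = j[in_sel],
                         weight = w[in_sel], cluster = lab[i[in_sel]])
  a <- pmin(lab[i[out_sel]], lab[j[out_sel]])
  b <- pmax(lab[i[out_sel]], lab[j[out_sel]])
  out_edges <- data.frame(i = i[out_sel], j = j[out_sel],
                          weight = w[out_sel], cluster_a = a, cluster_b = b)

  structure(list(n_cells = n,
                 clusters = sort(unique(lab)),
                 in_edges = in_edges,
                 out_edges = out_edges,
                 params = params),
            class = "ClusteringGraph")
}

#' @export
print.ClusteringGraph <- function(x, ...) {
  cat(sprintf("ClusteringGraph: %d cells, %d clusters, %d in-cluster / %d out-cluster edges\n",
              x$n_cells, length(x$clusters),
              nrow(x$in_edges), nrow(x$out_edges)))
  invisible(x)
}

#' Contract the clustering graph
#'
#' Collapses each cluster to a single node. Every surviving quantity is an
#' average of threshold exceedances:
#' \deqn{d_{ij} = \sum_{r_p \in E_{ij}} (r_p - \beta) / |E_{ij}|}
#' over the out-cluster edges between clusters i and j;
#' \deqn{w_i = \sum (\alpha - c) / k_i} over the `k_i` in-cluster edges of
#' cluster i (0 when `k_i = 0`); and \eqn{d_i = \sum_{j \in D(v_i)} d_{ij}}
#' over the neighbors of cluster node i (0 when isolated). Clusters with no
#' edges still appear as isolated nodes.
#'
#' @param G a [ClusteringGraph].
#' @return an object of class `ContractedGraph`: list with `nodes`
#'   (data.frame `cluster, w, d, k`) and `edges` (data.frame
#'   `cluster_a, cluster_b, d_ij, n_edges`).
#' @export
contract_graph <- function(G) {
  stopifnot(inherits(G, "ClusteringGraph"))
  alpha <- G$params$alpha
  beta <- G$params$beta
  clusters <- G$clusters

  k_i <- vapply(clusters, function(m) sum(G$in_edges$cluster == m), numeric(1))
  w_i <- vapply(clusters, function(m) {
    sel <- G$in_edges$cluster == m
    if (!any(sel)) 0 else sum(alpha - G$in_edges$weight[sel]) / sum(sel)
  }, numeric(1))

  if (nrow(G$out_edges) > 0L) {
    key <- interaction(G$out_edges$cluster_a, G$out_edges$cluster_b,
                       drop = TRUE)
    agg <- do.call(rbind, lapply(split(G$out_edges, key), function(e) {
      data.frame(cluster_a = e$cluster_a[1L], cluster_b = e$cluster_b[1L],
                 d_ij = sum(e$weight - beta) / nrow(e), n_edges = nrow(e))
    }))
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(cluster_a = integer(0), cluster_b = integer(0),
                      d_ij = numeric(0), n_edges = integer(0))
  }

  d_i <- vapply(clusters, function(m) {
    sel <- agg$cluster_a == m | agg$cluster_b == m
    if (!any(sel)) 0 else sum(agg$d_ij[sel])
  }, numeric(1))

  structure(list(nodes = data.frame(cluster = clusters, w = w_i, d = d_i,
                                    k = k_i),
                 edges = agg,
                 params = G$params),
            class = "ContractedGraph")
}

#' @export
print.ContractedGraph <- function(x, ...) {
  cat(sprintf("ContractedGraph: %d cluster nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' C-score of a contracted clustering graph
#'
#' `W_in` is the mean within-cluster weakness `w_i` and `D_out` the mean
#' leakage `d_i`, both averaged over all cluster nodes (isolated nodes
#' contribute zeros); the C-score is their product `W_in * D_out`. Lower is
#' better: a low score means same-cluster cells sit close in the consensus
#' and clusters barely leak into one another. A score of exactly 0 is
#' flagged (`zero_score = TRUE`): with over-aggressive thresholds both edge
#' sets can empty out, making all preprocessing methods indistinguishable.
#'
#' @param CG a [ContractedGraph].
#' @return an object of class `CScoreResult`: list with `W_in`, `D_out`,
#'   `c_score`, `n_clusters`, `zero_score`.
#' @export
c_score <- function(CG) {
  stopifnot(inherits(CG, "ContractedGraph"))
  n <- nrow(CG$nodes)
  if (n == 0L) stopf("contracted graph has no cluster nodes")
  W_in <- sum(CG$nodes$w) / n
  D_out <- sum(CG$nodes$d) / n
  cs <- W_in * D_out
  structure(list(W_in = W_in, D_out = D_out, c_score = cs,
                 n_clusters = n, zero_score = cs == 0),
            class = "CScoreResult")
}

#' @export
print.CScoreResult <- function(x, ...) {
  cat(sprintf("C-score = %.6g (W_in = %.6g, D_out = %.6g, %d clusters)%s\n",
              x$c_score, x$W_in, x$D_out, x$n_clusters,
              if (x$zero_score) " [zero-score warning]" else ""))
  invisible(x)
}

#' C-score straight from a consensus matrix and labels
#'
#' Chains [build_clustering_graph()], [contract_graph()] and [c_score()].
#'
#' @inheritParams build_clustering_graph
#' @return a `CScoreResult`.
#' @export
consensus_c_score <- function(C, T_, params = GraphParams()) {
  c_score(contract_graph(build_clustering_graph(C, T_, params)))
}

#' Export the clustering graph or its contraction as TSV edge/node lists
#'
#' For inspection and plotting outside R. The clustering graph is written as
#' a single edge list with a `type` column (`in`/`out`); the contracted
#' graph as a node table and an edge table.
#'
#' @param G a [ClusteringGraph] or [ContractedGraph].
#' @param path output path (for `ContractedGraph`, `path` is a prefix and
#'   `<path>_nodes.tsv` / `<path>_edges.tsv` are written).
#' @param cell_ids optional cell ids to label the cell columns with.
#' @return the path(s) written, invisibly.
#' @export
write_graph <- function(G, path, cell_ids = NULL) {
  tag <- function(idx) if (is.null(cell_ids)) idx else cell_ids[idx]
  if (inherits(G, "ClusteringGraph")) {
    ie <- G$in_edges
    oe <- G$out_edges
    df <- rbind(
      data.frame(cell_i = tag(ie$i), cell_j = tag(ie$j), weight = ie$weight,
                 type = rep("in", nrow(ie)), cluster = as.character(ie$cluster)),
      data.frame(cell_i = tag(oe$i), cell_j = tag(oe$j), weight = oe$weight,
                 type = rep("out", nrow(oe)),
                 cluster = paste(oe$cluster_a, oe$cluster_b, sep = "-")))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  stopifnot(inherits(G, "ContractedGraph"))
  paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
  utils::write.table(G$nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(G$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
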
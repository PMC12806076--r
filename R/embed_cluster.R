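# PCA embedding, k-nearest-neighbour graph, and Louvain community
# detection — the unsupervised clustering stage applied to an imputed
# matrix. Defaults (50 components, 15 Euclidean neighbours with union
# symmetrisation, resolution 1) are the de-facto defaults of the
# single-cell workflow family this pipeline follows; all are arguments.

#' Embed cells with principal component analysis
#'
#' Centers columns (no scaling: methylation levels already share the
#' \[0,1\] scale) and projects onto the top principal axes. Component signs
#' are fixed by making each axis's largest-magnitude loading positive, so
#' the embedding is fully deterministic.
#'
#' @param x An `imputed_matrix` or a plain numeric matrix (cells x
#'   features) with rownames as cell ids.
#' @param n_components Number of components requested (default 50);
#'   clipped to `min(n - 1, n_features)`.
#' @param seed Unused by the deterministic exact solver; accepted so the
#'   embedding stage has the same seeded signature as the clustering stage.
#' @return An object of class `embedding`: list with `cell_ids`, `coords`
#'   (n x D), `sdev` (component standard deviations).
#' @export
pca_embed <- function(x, n_components = 50L, seed = 0L) {
  if (inherits(x, "imputed_matrix")) {
    values <- x$values
    cell_ids <- x$cell_ids
  } else {
    values <- as.matrix(x)
    cell_ids <- rownames(values) %||% paste0("cell_", seq_len(nrow(values)))
  }
  n <- nrow(values)
  if (n < 2L) stopf("PCA needs at least 2 cells, got %d", n)
  if (any(!is.finite(values))) stopf("matrix contains non-finite values")
  d <- min(as.integer(n_components), n - 1L, ncol(values))
  if (d < 1L) stopf("cannot extract %s components", n_components)
  pr <- stats::prcomp(values, center = TRUE, scale. = FALSE, rank. = d)
  coords <- pr$x[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    load <- pr$rotation[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(cell_ids, paste0("PC", seq_len(d)))
  structure(list(cell_ids = cell_ids, coords = coords,
                 sdev = pr$sdev[seq_len(d)]),
            class = "embedding")
}

#' Build a k-nearest-neighbour graph over an embedding
#'
#' Connects each cell to its `k` nearest Euclidean neighbours; the
#' directed neighbour relation is symmetrised by union, giving an
#' undirected graph with unit edge weights. Distance ties are broken by
#' the lower cell index.
#'
#' @param emb An [pca_embed()] embedding.
#' @param k Number of neighbours per cell (default 15); must be `< n`.
#' @return An object of class `neighbor_graph`: list with `cell_ids`,
#'   `graph` (an igraph object), `k`.
#' @export
knn_graph <- function(emb, k = 15L) {
  stopifnot(inherits(emb, "embedding"))
  n <- nrow(emb$coords)
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  if (k >= n) stopf("k = %d must be smaller than the number of cells (%d)", k, n)
  d <- as.matrix(stats::dist(emb$coords))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(row) order(row)[seq_len(k)]))
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn))
  a <- pmin(from, to)
  b <- pmax(from, to)
  edges <- unique(cbind(a, b))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- emb$cell_ids
  structure(list(cell_ids = emb$cell_ids, graph = g, k = k),
            class = "neighbor_graph")
}

#' Cluster cells with the Louvain algorithm
#'
#' Runs Louvain modularity optimisation on the neighbour graph. The
#' community labels are arbitrary integers but stable for a fixed seed.
#'
#' @param ng A [knn_graph()] graph.
#' @param resolution Modularity resolution parameter (default 1).
#' @param seed RNG seed controlling the algorithm's sweep order.
#' @return A [partition] of the graph's cells.
#' @export
louvain_cluster <- function(ng, resolution = 1.0, seed = 0L) {
  stopifnot(inherits(ng, "neighbor_graph"))
  if (igraph::vcount(ng$graph) == 0L) stopf("empty graph")
  membership <- with_seed(seed, {
    cl <- igraph::cluster_louvain(ng$graph, resolution = resolution)
    igraph::membership(cl)
  })
  partition(ng$cell_ids, as.integer(membership))
}

#' Evaluate the (generalised) modularity of a labelled graph
#'
#' Direct implementation of Newman's modularity with a resolution
#' parameter, Q = (1/2m) * sum_ij (A_ij - gamma * d_i d_j / 2m) *
#' delta(c_i, c_j), computed from the edge list and degree sequence. Used
#' as an independent check that community detection output does maximise
#' something sensible.
#'
#' @param ng A [knn_graph()] graph.
#' @param part A [partition] labelling the same cells.
#' @param resolution Resolution gamma (default 1).
#' @return Modularity value (<= 1).
#' @export
graph_modularity <- function(ng, part, resolution = 1.0) {
  stopifnot(inherits(ng, "neighbor_graph"), inherits(part, "partition"))
  if (!setequal(ng$cell_ids, part$cell_ids)) {
    stopf("partition cells do not match graph cells")
  }
  labels <- part$labels[match(ng$cell_ids, part$cell_ids)]
  el <- igraph::as_edgelist(ng$graph, names = FALSE)
  w <- igraph::E(ng$graph)$weight %||% rep(1, nrow(el))
  m <- sum(w)
  if (m == 0) return(0)
  deg <- igraph::strength(ng$graph)
  within <- sum(w[labels[el[, 1L]] == labels[el[, 2L]]])
  null_term <- sum(vapply(split(deg, labels), sum, 0)^2) / (4 * m^2)
  within / m - resolution * null_term
}
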
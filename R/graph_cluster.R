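#' Shared-nearest-neighbor Jaccard graph
#'
#' PhenoGraph-style graph construction: for every cell, find its `k` nearest
#' neighbors (self excluded) under the Manhattan distance on the 2-D
#' embedding coordinates, then connect each pair of cells that appears in at
#' least one directed neighbor relation with an edge weighted by the Jaccard
#' coefficient of their two neighbor sets,
#' `J(u, v) = |N(u) ∩ N(v)| / |N(u) ∪ N(v)|`. Edges with `J = 0` are
#' omitted. Ties at the k-th distance are broken by ascending cell index,
#' so the graph is deterministic.
#'
#' @param e An `embedding` (or a cells x d coordinate matrix with rownames).
#' @param k Neighborhood size (default 50); must be `< cells`.
#' @param metric Distance metric; only `"manhattan"` is supported.
#' @return An object of class `cell_graph`: list with `edges` (tibble:
#'   `cell_u`, `cell_v`, `jaccard`), `cell_ids`, `k`, `metric`, and `nn`
#'   (the n x k neighbor-index matrix).
#' @export
knn_graph <- function(e, k = 50, metric = c("manhattan")) {
  metric <- match.arg(metric)
  coords <- if (inherits(e, "embedding")) e$coords else as.matrix(e)
  if (!all(is.finite(coords))) stop("non-finite embedding coordinates")
  n <- nrow(coords)
  if (k >= n) stop("k = ", k, " must be smaller than the number of cells (", n, ")")
  cell_ids <- rownames(coords)
  if (is.null(cell_ids)) cell_ids <- as.character(seq_len(n))
  D <- as.matrix(stats::dist(coords, method = "manhattan"))
  nn <- matrix(0L, n, k)
  idx <- seq_len(n)
  for (i in idx) {
    d <- D[i, ]
    d[i] <- Inf                      # self excluded
    ord <- order(d, idx)             # ties broken by ascending cell index
    nn[i, ] <- sort(ord[seq_len(k)]) # sorted for fast set intersection
  }
  # union of directed neighbor relations, as unordered pairs
  u <- rep(idx, each = k)
  v <- as.integer(t(nn))
  lo <- pmin(u, v); hi <- pmax(u, v)
  keep <- !duplicated(lo * (n + 1) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  w <- jaccard_pairs_cpp(nn, lo, hi)
  pos <- w > 0
  edges <- tibble::tibble(cell_u = cell_ids[lo[pos]],
                          cell_v = cell_ids[hi[pos]],
                          jaccard = w[pos])
  structure(list(edges = edges, cell_ids = cell_ids, k = k, metric = metric,
                 nn = nn),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("<cell_graph> %d cells, %d edges (k = %d, %s distance)\n",
              length(x$cell_ids), nrow(x$edges), x$k, x$metric))
  invisible(x)
}

#' @rdname knn_graph
#' @param x A `cell_graph`.
#' @param ... Unused.
#' @return `tidy()`: the edge tibble.
#' @export
tidy.cell_graph <- function(x, ...) x$edges

as_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = g$edges$cell_u, to = g$edges$cell_v,
               weight = g$edges$jaccard),
    directed = FALSE,
    vertices = data.frame(name = g$cell_ids))
  ig
}

#' Louvain community detection on a cell graph
#'
#' Partitions the Jaccard-weighted graph by greedy modularity optimization
#' (the Louvain method, delegated to igraph). Cluster ids are contiguous
#' integers from 0, numbered by first appearance in cell order. Cells with
#' no positive-Jaccard edge become singleton clusters.
#'
#' @param g A `cell_graph`.
#' @param seed Seed pinning any internal randomization.
#' @return An object of class `cell_clustering`: list with `labels` (tibble:
#'   `cell_id`, `cluster`), `n_clusters`, `modularity`.
#' @export
louvain_cluster <- function(g, seed = 0) {
  stopifnot(inherits(g, "cell_graph"))
  n <- length(g$cell_ids)
  if (nrow(g$edges) == 0) {
    warning("graph has no edges; every cell becomes its own cluster")
    membership <- seq_len(n)
    modularity <- NA_real_
  } else {
    ig <- as_igraph(g)
    set.seed(seed)
    cl <- igraph::cluster_louvain(ig, weights = igraph::E(ig)$weight)
    membership <- igraph::membership(cl)[g$cell_ids]
    modularity <- igraph::modularity(ig, membership,
                                     weights = igraph::E(ig)$weight)
  }
  # contiguous 0-based ids in order of first appearance
  labels <- match(membership, unique(membership)) - 1L
  structure(list(labels = tibble::tibble(cell_id = g$cell_ids,
                                         cluster = labels),
                 n_clusters = length(unique(labels)),
                 modularity = modularity),
            class = "cell_clustering")
}

#' @export
print.cell_clustering <- function(x, ...) {
  cat(sprintf("<cell_clustering> %d cells in %d clusters (modularity %.3f)\n",
              nrow(x$labels), x$n_clusters, x$modularity))
  invisible(x)
}

#' @rdname louvain_cluster
#' @param x A `cell_clustering`.
#' @param ... Unused.
#' @return `tidy()`: tibble with `cell_id`, `cluster`.
#' @export
tidy.cell_clustering <- function(x, ...) x$labels

#' @rdname louvain_cluster
#' @export
glance.cell_clustering <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$labels), n_clusters = x$n_clusters,
                 modularity = x$modularity)
}

#' Write graph and clustering artifacts
#'
#' @param g A `cell_graph`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  readr::write_tsv(g$edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param cl A `cell_clustering`.
#' @export
write_clusters <- function(cl, path) {
  readr::write_tsv(cl$labels, path, progress = FALSE)
  invisible(path)
}
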
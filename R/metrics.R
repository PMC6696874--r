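#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same cells
#' (Hubert-Arabie form). Identical partitions (up to relabeling) give 1;
#' the expected value under independent random labelings is 0. Binomial
#' coefficients are accumulated as exact doubles (counts up to ~5e4 cells
#' stay far below 2^53, so the arithmetic is exact).
#'
#' @param labels_a,labels_b One label per cell; any atomic type.
#' @return The ARI, a single number.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors have different lengths")
  }
  n <- length(labels_a)
  stopifnot(n >= 2)
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(as.numeric(tab)))
  a <- sum(choose2(as.numeric(rowSums(tab))))
  b <- sum(choose2(as.numeric(colSums(tab))))
  total <- choose2(n)
  expected <- a * b / total
  max_term <- (a + b) / 2
  if (max_term == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_term - expected)
}

#' Cluster purity
#'
#' For each cluster, the number of cells from its most common true class is
#' counted; purity is the sum of these majority counts divided by the total
#' number of cells. Purity is 1 exactly when every cluster is class-pure.
#'
#' @param clusters,classes One label per cell.
#' @return Purity in (0, 1].
#' @export
purity <- function(clusters, classes) {
  if (length(clusters) != length(classes)) {
    stop("label vectors have different lengths")
  }
  stopifnot(length(clusters) >= 1)
  tab <- table(clusters, classes)
  sum(apply(tab, 1, max)) / length(clusters)
}

#' Mean intra-type embedding distance
#'
#' For each cell type, the mean Euclidean distance over all unordered
#' within-type pairs of cells on the (rescaled) embedding coordinates — the
#' standard read-out of how tightly an embedding groups cells of the same
#' type. Types with fewer than 2 cells are reported as `NA`. The overall
#' summary is the unweighted mean across types (so small types are not
#' swamped); a cell-weighted variant is available.
#'
#' @param e An `embedding` (rescaling to \[-1, 1\] is conventional; a
#'   warning is emitted if `e` is not rescaled) or a cells x 2 coordinate
#'   matrix.
#' @param classes One type label per cell, in embedding row order.
#' @param max_pairs Classes with more unordered pairs than this are
#'   subsampled (seeded) instead of enumerated exactly.
#' @param seed Seed for pair subsampling.
#' @param weighted Use a cell-count-weighted overall mean instead of the
#'   unweighted mean across types.
#' @return A list with `per_type` (tibble: `cell_type`, `n_cells`,
#'   `mean_distance`) and `overall` (single number).
#' @export
intra_type_distance <- function(e, classes, max_pairs = 1e6, seed = 0,
                                weighted = FALSE) {
  coords <- if (inherits(e, "embedding")) {
    if (!e$rescaled) warning("embedding is not rescaled to [-1, 1]")
    e$coords
  } else as.matrix(e)
  stopifnot(nrow(coords) == length(classes))
  types <- sort(unique(as.character(classes)))
  per_type <- purrr::map_dfr(types, function(tp) {
    xy <- coords[classes == tp, , drop = FALSE]
    m <- nrow(xy)
    if (m < 2) {
      return(tibble::tibble(cell_type = tp, n_cells = m,
                            mean_distance = NA_real_))
    }
    n_pairs <- m * (m - 1) / 2
    d <- if (n_pairs <= max_pairs) {
      mean(stats::dist(xy))
    } else {
      set.seed(seed)
      i <- sample.int(m, max_pairs, replace = TRUE)
      j <- sample.int(m, max_pairs, replace = TRUE)
      ok <- i != j
      mean(sqrt(rowSums((xy[i[ok], , drop = FALSE] -
                           xy[j[ok], , drop = FALSE])^2)))
    }
    tibble::tibble(cell_type = tp, n_cells = m, mean_distance = d)
  })
  valid <- !is.na(per_type$mean_distance)
  overall <- if (weighted) {
    stats::weighted.mean(per_type$mean_distance[valid],
                         per_type$n_cells[valid])
  } else {
    mean(per_type$mean_distance[valid])
  }
  list(per_type = per_type, overall = overall)
}

#' Cell-type annotation accuracy
#'
#' Percentage of cells whose cluster-assigned cell type equals their true
#' type, plus per-type recall. An optional grouping map collapses
#' fine-grained labels (e.g., several T-cell subsets) into broader groups
#' before comparison; it is applied to both vectors.
#'
#' @param assigned Cell-type label per cell (via its cluster's annotation).
#' @param truth True cell-type label per cell.
#' @param group_map Optional named character vector mapping original labels
#'   to group labels; labels present in the data but missing from the map
#'   raise an error listing them.
#' @return A list with `accuracy_pct` (percentage) and `per_type` (tibble:
#'   `cell_type`, `n_cells`, `recall`).
#' @export
annotation_accuracy <- function(assigned, truth, group_map = NULL) {
  if (length(assigned) != length(truth)) {
    stop("label vectors have different lengths")
  }
  assigned <- as.character(assigned)
  truth <- as.character(truth)
  if (!is.null(group_map)) {
    unmapped <- setdiff(unique(c(assigned, truth)), names(group_map))
    if (length(unmapped)) {
      stop("labels missing from group_map: ",
           paste(unmapped, collapse = ", "))
    }
    assigned <- unname(group_map[assigned])
    truth <- unname(group_map[truth])
  }
  correct <- assigned == truth
  per_type <- tibble::tibble(cell_type = truth, correct = correct) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     recall = mean(.data$correct), .groups = "drop")
  list(accuracy_pct = 100 * mean(correct), per_type = per_type)
}

#' Bundle evaluation metrics for a clustering run
#'
#' Convenience wrapper computing ARI, purity, and intra-type distances (and
#' annotation accuracy when per-cell assigned types are available) in one
#' tibble-friendly structure, writable as JSON.
#'
#' @param cl A `cell_clustering`.
#' @param truth Tibble with `cell_id` and a true `cell_type` per cell.
#' @param e Optional rescaled `embedding` for intra-type distances.
#' @param assigned Optional tibble with `cell_id`, `assigned_type`.
#' @param group_map Optional label grouping map (see
#'   [annotation_accuracy()]).
#' @return A list of class `metrics_report`.
#' @export
evaluate_clustering <- function(cl, truth, e = NULL, assigned = NULL,
                                group_map = NULL) {
  stopifnot(inherits(cl, "cell_clustering"))
  truth <- tibble::as_tibble(truth)
  merged <- dplyr::inner_join(cl$labels, truth, by = "cell_id")
  if (nrow(merged) < nrow(cl$labels)) {
    warning(nrow(cl$labels) - nrow(merged), " clustered cells lack a truth label")
  }
  out <- list(
    ari = adjusted_rand_index(merged$cluster, merged$cell_type),
    purity = purity(merged$cluster, merged$cell_type),
    n_cells = nrow(merged),
    n_clusters = cl$n_clusters
  )
  if (!is.null(e)) {
    idx <- match(merged$cell_id, rownames(e$coords))
    itd <- intra_type_distance(e$coords[idx, , drop = FALSE],
                               merged$cell_type)
    out$intra_type_distance <- itd$overall
    out$per_type_distance <- itd$per_type
  }
  if (!is.null(assigned)) {
    asg <- dplyr::inner_join(merged, tibble::as_tibble(assigned),
                             by = "cell_id")
    acc <- annotation_accuracy(asg$assigned_type, asg$cell_type, group_map)
    out$accuracy_pct <- acc$accuracy_pct
    out$per_type_recall <- acc$per_type
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ARI %.3f, purity %.3f over %d cells in %d clusters\n",
              x$ari, x$purity, x$n_cells, x$n_clusters))
  if (!is.null(x$accuracy_pct)) {
    cat(sprintf("  annotation accuracy %.1f%%\n", x$accuracy_pct))
  }
  invisible(x)
}

#' @rdname evaluate_clustering
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(ari = x$ari, purity = x$purity,
                 accuracy_pct = x$accuracy_pct %||% NA_real_,
                 intra_type_distance = x$intra_type_distance %||% NA_real_,
                 n_cells = x$n_cells, n_clusters = x$n_clusters)
}

#' Write a metrics report as JSON
#'
#' @param x A `metrics_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(x, path) {
  out <- list(ari = x$ari, purity = x$purity,
              n_cells = x$n_cells, n_clusters = x$n_clusters)
  if (!is.null(x$accuracy_pct)) out$accuracy_pct <- x$accuracy_pct
  if (!is.null(x$intra_type_distance)) {
    out$intra_type_distance <- x$intra_type_distance
    out$per_type_distance <- x$per_type_distance
  }
  if (!is.null(x$per_type_recall)) out$per_type_recall <- x$per_type_recall
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
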
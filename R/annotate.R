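#' Per-cluster gf-icf gene signatures
#'
#' For each cluster, genes are scored by the sum of their gf-icf weights
#' across the cluster's cells and the top `size` genes with positive
#' aggregate score are retained, in descending score order (ties broken
#' lexicographically by gene id). Because gf-icf up-weights genes specific
#' to a subpopulation, these signatures act as marker sets for the cluster.
#'
#' @param g A `gficf_matrix`.
#' @param cl A `cell_clustering` (or tibble with `cell_id`, `cluster`).
#' @param size Signature size (default 100).
#' @return An object of class `cluster_signatures`: tibble with columns
#'   `cluster`, `rank`, `gene_id`, `score`.
#' @export
cluster_signature <- function(g, cl, size = 100) {
  stopifnot(inherits(g, "gficf_matrix"))
  labels <- if (inherits(cl, "cell_clustering")) cl$labels else
    tibble::as_tibble(cl)
  unknown <- setdiff(labels$cell_id, g$cell_ids)
  if (length(unknown)) {
    stop("clustering contains cell ids absent from the gf-icf matrix: ",
         paste(head(unknown, 5), collapse = ", "))
  }
  sig <- labels |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_modify(function(d, key) {
      agg <- Matrix::rowSums(g$weights[, d$cell_id, drop = FALSE])
      ord <- order(-agg, g$gene_ids)
      keep <- ord[agg[ord] > 0]
      keep <- head(keep, size)
      tibble::tibble(rank = seq_along(keep),
                     gene_id = g$gene_ids[keep],
                     score = as.numeric(agg[keep]))
    }) |>
    dplyr::ungroup()
  structure(sig, class = c("cluster_signatures", class(sig)))
}

#' Write cluster signatures in GMT format
#'
#' One line per cluster: set name, description, then the gene ids in rank
#' order, tab-separated — the conventional interchange format for gene sets.
#'
#' @param sig A `cluster_signatures` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sig, path) {
  lines <- sig |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(line = paste(c(paste0("cluster_", .data$cluster[1]),
                                    "gf-icf signature",
                                    .data$gene_id),
                                  collapse = "\t"),
                     .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}

#' Bulk reference expression panel
#'
#' A genes x samples expression matrix where every sample carries a
#' cell-type label, used as the annotation vocabulary for cluster
#' assignment. Panels of FACS-purified ("pure") bulk profiles are the usual
#' source.
#'
#' @param expression Numeric genes x samples matrix with gene ids as
#'   rownames and sample ids as colnames.
#' @param sample_cell_type Character vector, one cell-type label per sample
#'   (column).
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(expression, sample_cell_type) {
  expression <- as.matrix(expression)
  stopifnot(ncol(expression) == length(sample_cell_type),
            !is.null(rownames(expression)))
  if (length(unique(sample_cell_type)) < 2) {
    warning("reference panel covers fewer than 2 cell types; ",
            "annotation will not be discriminative")
  }
  structure(list(expression = expression,
                 sample_cell_type = as.character(sample_cell_type),
                 cell_types = sort(unique(as.character(sample_cell_type)))),
            class = "reference_panel")
}

#' Read a reference panel from TSV
#'
#' @param expression_path TSV of expression, first column gene ids, header
#'   row of sample ids.
#' @param labels_path Two-column TSV mapping sample id to cell type
#'   (columns `sample_id`, `cell_type`; a header is required).
#' @return A [reference_panel].
#' @export
read_reference_panel <- function(expression_path, labels_path) {
  tab <- readr::read_tsv(expression_path, show_col_types = FALSE,
                         progress = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab[[1]]
  map <- readr::read_tsv(labels_path, show_col_types = FALSE,
                         progress = FALSE)
  labs <- setNames(as.character(map[[2]]), as.character(map[[1]]))
  missing <- setdiff(colnames(expr), names(labs))
  if (length(missing)) {
    stop("samples without a cell-type label: ",
         paste(head(missing, 5), collapse = ", "))
  }
  reference_panel(expr, labs[colnames(expr)])
}

#' Preranked gene set enrichment score
#'
#' Classical GSEA running-sum statistic: walking down the ranked gene list,
#' the running sum increases by `|stat|^weight_exponent` (normalized over
#' the set's hits) at each gene in the set and decreases by
#' `1 / (n - hits)` at each miss. The enrichment score is the running-sum
#' value of maximal absolute deviation from zero (signed). With
#' `weight_exponent = 0` this is the Kolmogorov-Smirnov-like unweighted
#' statistic, whose maximum value 1 is attained when the set occupies
#' exactly the top of the list.
#'
#' @param ranked_genes Character vector of gene ids in ranking order (best
#'   first).
#' @param stats Numeric ranking statistic aligned with `ranked_genes`
#'   (required when `weight_exponent > 0`).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Exponent on `|stat|` for hit increments
#'   (default 1, the classical weighted statistic).
#' @return The enrichment score in \[-1, 1\], or `NA_real_` when the set
#'   does not intersect the list.
#' @export
enrichment_score <- function(ranked_genes, stats = NULL, gene_set,
                             weight_exponent = 1) {
  n <- length(ranked_genes)
  hit <- ranked_genes %in% gene_set
  n_hit <- sum(hit)
  if (n_hit == 0) return(NA_real_)
  if (n_hit == n) stop("gene_set covers the whole ranked list")
  if (weight_exponent > 0) {
    if (is.null(stats)) stop("stats required when weight_exponent > 0")
    w <- abs(stats)^weight_exponent
  } else {
    w <- rep(1, n)
  }
  inc <- ifelse(hit, w / sum(w[hit]), 0)
  dec <- ifelse(hit, 0, 1 / (n - n_hit))
  running <- cumsum(inc - dec)
  running[which.max(abs(running))]
}

# null ES distribution for random gene sets of a given size on a fixed
# ranked list; used for NES normalization and permutation p-values
null_es <- function(ranked_genes, stats, set_size, n_permutations,
                    weight_exponent) {
  vapply(seq_len(n_permutations), function(i) {
    enrichment_score(ranked_genes, stats,
                     sample(ranked_genes, set_size),
                     weight_exponent = weight_exponent)
  }, numeric(1))
}

# per-cell-type ranked gene lists: genes ranked by log2 fold-change of the
# type's mean expression versus the mean of all other types (pseudo-count 1)
panel_rankings <- function(panel) {
  expr <- panel$expression
  types <- panel$cell_types
  means <- vapply(types, function(t) {
    rowMeans(expr[, panel$sample_cell_type == t, drop = FALSE])
  }, numeric(nrow(expr)))
  lapply(setNames(types, types), function(t) {
    rest <- rowMeans(means[, colnames(means) != t, drop = FALSE])
    lfc <- log2((means[, t] + 1) / (rest + 1))
    ord <- order(-lfc, rownames(expr))
    list(genes = rownames(expr)[ord], stats = lfc[ord])
  })
}

#' Annotate clusters by GSEA against a bulk reference panel
#'
#' For every reference cell type, genes are ranked by the log2 fold-change
#' of that type's mean expression against the mean of all other types
#' (pseudo-count 1). Each cluster's signature is scored on each ranked list
#' with the running-sum enrichment score; scores are normalized by a
#' gene-permutation null (`NES = ES / mean(same-sign null ES)`) with a
#' permutation p-value. The cluster is assigned the cell type with the
#' highest NES (ties broken by raw ES, then lexicographic type name).
#' Clusters whose signature shares no genes with the panel are annotated
#' `"unassigned"`.
#'
#' @param sig A `cluster_signatures` tibble from [cluster_signature()].
#' @param panel A [reference_panel].
#' @param n_permutations Gene-permutation count for the null (default 1000).
#' @param seed Seed for the permutation null.
#' @param weight_exponent Passed to [enrichment_score()].
#' @return An object of class `cluster_annotation`: list with `table`
#'   (tibble: `cluster`, `cell_type`, `es`, `nes`, `p_value`, `assigned`)
#'   and `assignments` (tibble: `cluster`, `assigned_type`).
#' @export
annotate_clusters <- function(sig, panel, n_permutations = 1000, seed = 0,
                              weight_exponent = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  rankings <- panel_rankings(panel)
  panel_genes <- rownames(panel$expression)
  shared <- length(intersect(unique(sig$gene_id), panel_genes))
  if (shared < 20) {
    warning("only ", shared, " genes shared between signatures and panel")
  }
  set.seed(seed)
  null_cache <- new.env(parent = emptyenv())
  clusters <- sort(unique(sig$cluster))
  rows <- list()
  assignments <- list()
  for (q in clusters) {
    genes <- sig$gene_id[sig$cluster == q]
    genes <- intersect(genes, panel_genes)
    if (length(genes) == 0) {
      assignments[[length(assignments) + 1]] <-
        tibble::tibble(cluster = q, assigned_type = "unassigned")
      next
    }
    per_type <- purrr::map_dfr(names(rankings), function(tp) {
      rk <- rankings[[tp]]
      es <- enrichment_score(rk$genes, rk$stats, genes, weight_exponent)
      key <- paste(tp, length(genes))
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- null_es(rk$genes, rk$stats, length(genes),
                                     n_permutations, weight_exponent)
      }
      null <- null_cache[[key]]
      same_sign <- if (es >= 0) null[null > 0] else -null[null < 0]
      nes <- if (length(same_sign)) {
        sign(es) * abs(es) / mean(same_sign)
      } else NA_real_
      p <- (1 + sum(same_sign >= abs(es))) / (1 + length(same_sign))
      tibble::tibble(cluster = q, cell_type = tp, es = es, nes = nes,
                     p_value = p)
    })
    per_type <- dplyr::arrange(per_type, dplyr::desc(.data$nes),
                               dplyr::desc(.data$es), .data$cell_type)
    per_type$assigned <- seq_len(nrow(per_type)) == 1
    rows[[length(rows) + 1]] <- per_type
    assignments[[length(assignments) + 1]] <-
      tibble::tibble(cluster = q, assigned_type = per_type$cell_type[1])
  }
  structure(list(table = dplyr::bind_rows(rows),
                 assignments = dplyr::bind_rows(assignments)),
            class = "cluster_annotation")
}

#' @export
print.cluster_annotation <- function(x, ...) {
  cat("<cluster_annotation>\n")
  print(x$assignments)
  invisible(x)
}

#' @rdname annotate_clusters
#' @param x A `cluster_annotation`.
#' @param ... Unused.
#' @return `tidy()`: the full per-cluster, per-type enrichment table.
#' @export
tidy.cluster_annotation <- function(x, ...) x$table

#' Write the annotation table as TSV
#'
#' @param ann A `cluster_annotation`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(ann$table, path, progress = FALSE)
  invisible(path)
}
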
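#' Configuration for the synthetic UMI-count simulator
#'
#' The simulator emulates the structure the pipeline is built for: a sparse,
#' zero-inflated genes x cells UMI matrix with planted cell types that
#' differ through marker genes, variable per-cell sequencing depth, an
#' expression-dependent dropout process, and a dedicated mitochondrial gene
#' block (ids `MT-1`, `MT-2`, ...) so quality-control filters are exercised.
#'
#' Defaults describe a small but realistic droplet experiment: 5 cell types
#' of 200 cells each, 2,000 genes, 20 markers per type elevated 8-fold,
#' strongly skewed log-normal baseline expression rates (a few genes carry
#' most of the counts, as in real UMI data), depths uniform in 2,500-7,000
#' UMI (so nearly all cells clear the conventional 1,500-UMI / 500-gene QC
#' cut after dropout), logistic expression-dependent dropout giving roughly
#' two-thirds zero entries, and 1-8% mitochondrial content (below the 10%
#' QC ceiling).
#'
#' @param n_types Number of planted cell types.
#' @param cells_per_type Cells per type.
#' @param n_genes Total genes, including the mitochondrial block.
#' @param markers_per_type Marker genes per type (disjoint across types).
#' @param marker_fold Expression multiplier on a type's markers (> 1).
#' @param base_log_mean,base_log_sd Log-normal parameters of baseline
#'   per-gene expression rates.
#' @param depth_range Per-cell total UMI drawn uniformly from this range
#'   (before dropout).
#' @param dropout_intercept,dropout_slope Dropout probability for a
#'   gene/cell entry is `plogis(intercept - slope * log1p(expected_count))`:
#'   lowly expressed entries drop out more often.
#' @param n_mito_genes Size of the mitochondrial gene block.
#' @param mito_fraction_range Per-cell target mitochondrial UMI fraction,
#'   drawn uniformly from this range.
#' @param seed Simulation seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_types = 5, cells_per_type = 200, n_genes = 2000,
                       markers_per_type = 20, marker_fold = 8,
                       base_log_mean = 0, base_log_sd = 1.8,
                       depth_range = c(2500, 7000),
                       dropout_intercept = -0.5, dropout_slope = 1,
                       n_mito_genes = 13,
                       mito_fraction_range = c(0.01, 0.08),
                       seed = 0) {
  stopifnot(n_types >= 1, cells_per_type >= 1, marker_fold >= 1,
            depth_range[1] <= depth_range[2], depth_range[1] >= 1,
            mito_fraction_range[1] <= mito_fraction_range[2],
            mito_fraction_range[1] >= 0, mito_fraction_range[2] < 1,
            n_mito_genes >= 0)
  if (n_types * markers_per_type > n_genes - n_mito_genes) {
    stop("infeasible config: markers (", n_types * markers_per_type,
         ") exceed available non-mitochondrial genes (",
         n_genes - n_mito_genes, ")")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a sparse UMI count matrix with planted cell types
#'
#' Per cell: a depth is drawn uniformly from `depth_range`; expected gene
#' proportions are the log-normal baseline rates with that cell's type
#' markers multiplied by `marker_fold` and the mitochondrial block scaled to
#' the cell's target mito fraction, renormalized; counts are drawn
#' multinomially conditional on the depth (so depth is exactly controlled);
#' expression-dependent dropout then zeroes entries with probability
#' `plogis(intercept - slope * log1p(expected count))`. A cell zeroed out
#' entirely by dropout has its largest pre-dropout entry restored, so every
#' cell retains depth >= 1. Fully reproducible from the seed.
#'
#' @param cfg A [sim_config].
#' @return A list of class `sim_result` with `counts` (a [raw_counts]),
#'   `labels` (tibble: `cell_id`, `cell_type`), `markers` (tibble:
#'   `gene_id`, `cell_type`), and `base_rates` (named per-gene vector).
#' @export
simulate_counts <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_cells <- cfg$n_types * cfg$cells_per_type
  n_plain <- cfg$n_genes - cfg$n_mito_genes
  gene_ids <- c(sprintf("G%04d", seq_len(n_plain)),
                if (cfg$n_mito_genes > 0) paste0("MT-", seq_len(cfg$n_mito_genes)))
  types <- paste0("type", seq_len(cfg$n_types))
  cell_type <- rep(types, each = cfg$cells_per_type)
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))

  base <- rlnorm(cfg$n_genes, cfg$base_log_mean, cfg$base_log_sd)
  names(base) <- gene_ids
  mito_idx <- if (cfg$n_mito_genes > 0) n_plain + seq_len(cfg$n_mito_genes)
              else integer(0)

  # markers must be detectable to act as markers: sample them from genes
  # with above-median baseline rate (an 8-fold elevation of a gene that is
  # never observed would plant no recoverable signal)
  eligible <- which(base[seq_len(n_plain)] >= stats::median(base[seq_len(n_plain)]))
  marker_idx <- matrix(sample(eligible, cfg$n_types * cfg$markers_per_type),
                       nrow = cfg$n_types)
  markers <- tibble::tibble(
    gene_id = gene_ids[as.integer(t(marker_idx))],
    cell_type = rep(types, each = cfg$markers_per_type))

  # per-type expected proportions over non-mito genes
  type_props <- vapply(seq_len(cfg$n_types), function(t) {
    r <- base
    r[marker_idx[t, ]] <- r[marker_idx[t, ]] * cfg$marker_fold
    r[mito_idx] <- 0
    r / sum(r)
  }, numeric(cfg$n_genes))

  mito_props <- if (length(mito_idx)) base[mito_idx] / sum(base[mito_idx])
                else numeric(0)

  depths <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n_cells,
                   replace = TRUE)
  mito_frac <- runif(n_cells, cfg$mito_fraction_range[1],
                     cfg$mito_fraction_range[2])

  tri_i <- vector("list", n_cells)
  tri_x <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    t <- match(cell_type[j], types)
    mito_umi <- if (length(mito_idx)) round(depths[j] * mito_frac[j]) else 0
    plain_umi <- depths[j] - mito_umi
    expected <- type_props[, t] * plain_umi
    counts <- as.integer(rmultinom(1, plain_umi, type_props[, t]))
    if (mito_umi > 0) {
      counts[mito_idx] <- as.integer(rmultinom(1, mito_umi, mito_props))
      expected[mito_idx] <- mito_props * mito_umi
    }
    p_drop <- stats::plogis(cfg$dropout_intercept -
                              cfg$dropout_slope * log1p(expected))
    nz <- which(counts > 0)
    drop <- nz[runif(length(nz)) < p_drop[nz]]
    kept <- counts
    kept[drop] <- 0L
    if (all(kept == 0)) {          # degeneracy guard: depth >= 1 per cell
      top <- nz[which.max(counts[nz])]
      kept[top] <- counts[top]
    }
    keep_idx <- which(kept > 0)
    tri_i[[j]] <- keep_idx
    tri_x[[j]] <- kept[keep_idx]
  }
  lens <- lengths(tri_i)
  m <- Matrix::sparseMatrix(i = unlist(tri_i),
                            j = rep.int(seq_len(n_cells), lens),
                            x = unlist(tri_x),
                            dims = c(cfg$n_genes, n_cells))
  structure(list(counts = raw_counts(m, gene_ids, cell_ids),
                 labels = tibble::tibble(cell_id = cell_ids,
                                         cell_type = cell_type),
                 markers = markers,
                 base_rates = base,
                 config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d types x %d cells, %d genes (seed %d)\n",
              x$config$n_types, x$config$cells_per_type, x$config$n_genes,
              x$config$seed))
  invisible(x)
}

#' Simulate a matched bulk reference panel
#'
#' Builds "pure" bulk expression profiles on the same gene namespace as the
#' simulated single cells: for every planted type, samples carry the
#' baseline rates with that type's markers elevated by the simulation's
#' `marker_fold`, multiplied by log-normal noise and scaled to counts per
#' million. With `noise_sd = 0` each type's fold-change ranking places its
#' own markers exactly at the top.
#'
#' @param sim A `sim_result` from [simulate_counts()].
#' @param n_samples_per_type Bulk samples per cell type (default 3).
#' @param noise_sd Log-normal noise standard deviation (default 0.25).
#' @param seed Seed for the noise draws.
#' @return A [reference_panel] on the simulation's gene namespace.
#' @export
simulate_reference_panel <- function(sim, n_samples_per_type = 3,
                                     noise_sd = 0.25, seed = 0) {
  stopifnot(inherits(sim, "sim_result"))
  set.seed(seed)
  cfg <- sim$config
  gene_ids <- names(sim$base_rates)
  types <- unique(sim$labels$cell_type)
  cols <- list()
  labs <- character(0)
  for (tp in types) {
    mk <- sim$markers$gene_id[sim$markers$cell_type == tp]
    mean_expr <- sim$base_rates
    mean_expr[mk] <- mean_expr[mk] * cfg$marker_fold
    for (s in seq_len(n_samples_per_type)) {
      noise <- if (noise_sd > 0) rlnorm(length(mean_expr), 0, noise_sd)
               else 1
      x <- mean_expr * noise
      cols[[length(cols) + 1]] <- x / sum(x) * 1e6
      labs <- c(labs, tp)
    }
  }
  expr <- do.call(cbind, cols)
  rownames(expr) <- gene_ids
  colnames(expr) <- sprintf("%s_s%d", labs, stats::ave(seq_along(labs),
                                                       labs, FUN = seq_along))
  reference_panel(expr, labs)
}

#' Write simulation fixtures to disk
#'
#' Writes the count matrix in the 10x-style triplet layout plus truth
#' labels and the marker map as TSV — the same formats [read_counts()]
#' consumes.
#'
#' @param sim A `sim_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, dir, format = "mtx_triplet")
  readr::write_tsv(sim$labels, file.path(dir, "truth_labels.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$markers, file.path(dir, "markers.tsv"),
                   progress = FALSE)
  invisible(dir)
}
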
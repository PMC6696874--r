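#' Raw UMI count matrix container
#'
#' Constructs the basic container used throughout the package: a sparse
#' genes x cells matrix of non-negative integer UMI counts with unique gene
#' and cell identifiers. Genes are always rows and cells columns.
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   genes in rows, cells in columns.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell barcodes (columns).
#' @return An object of class `raw_counts`: a list with elements `counts`
#'   (a `dgCMatrix`), `gene_ids` and `cell_ids`.
#' @export
raw_counts <- function(counts, gene_ids = rownames(counts),
                       cell_ids = colnames(counts)) {
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (!inherits(counts, "Matrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- as(as(as(counts, "CsparseMatrix"), "generalMatrix"), "dMatrix")
  if (nrow(counts) != length(gene_ids) || ncol(counts) != length(cell_ids)) {
    stop("dimension mismatch between counts and identifier lists")
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != trunc(x)))) {
    stop("non-integer count: entries must be non-negative integers")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("<raw_counts> %d genes x %d cells, %.1f%% zero entries\n",
              nrow(x$counts), ncol(x$counts),
              100 * (1 - Matrix::nnzero(x$counts) /
                       (as.numeric(nrow(x$counts)) * ncol(x$counts)))))
  invisible(x)
}

#' @export
dim.raw_counts <- function(x) dim(x$counts)

#' Read a UMI count matrix from disk
#'
#' Reads either a 10x Genomics v2 plain-text layout (`matrix.mtx` in Matrix
#' Market coordinate format plus `genes.tsv` and `barcodes.tsv` sidecars) or
#' a dense delimited table with gene identifiers in the first column and a
#' header row of cell identifiers. File order of genes and cells is
#' preserved; fractional or negative entries are rejected.
#'
#' @param path For `format = "mtx_triplet"`, either the directory containing
#'   `matrix.mtx`, `genes.tsv` and `barcodes.tsv`, or the path of the `.mtx`
#'   file itself (sidecars are looked up next to it). For
#'   `format = "dense_table"`, the path of the TSV/CSV file.
#' @param format `"mtx_triplet"` or `"dense_table"`.
#' @param sep Field separator for dense tables; guessed from the file
#'   extension (`","` for `.csv`, tab otherwise) when `NULL`.
#' @return A [raw_counts] object.
#' @export
read_counts <- function(path, format = c("mtx_triplet", "dense_table"),
                        sep = NULL) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    if (dir.exists(path)) {
      mtx <- file.path(path, "matrix.mtx")
      dirn <- path
    } else {
      mtx <- path
      dirn <- dirname(path)
    }
    genes_f <- file.path(dirn, "genes.tsv")
    barcodes_f <- file.path(dirn, "barcodes.tsv")
    for (f in c(mtx, genes_f, barcodes_f)) {
      if (!file.exists(f)) stop("missing companion file: ", f)
    }
    m <- Matrix::readMM(mtx)
    genes <- readr::read_tsv(genes_f, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_character()), progress = FALSE)
    barcodes <- readr::read_tsv(barcodes_f, col_names = FALSE,
                                col_types = readr::cols(.default = readr::col_character()),
                                progress = FALSE)
    if (nrow(genes) != nrow(m) || nrow(barcodes) != ncol(m)) {
      stop("dimension mismatch between matrix and gene/barcode lists")
    }
    raw_counts(m, gene_ids = genes[[1]], cell_ids = barcodes[[1]])
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- readr::read_delim(path, delim = sep,
                             col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE, show_col_types = FALSE)
    ids <- tab[[1]]
    m <- vapply(tab[-1], function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(tab)))
    m <- matrix(m, nrow = nrow(tab),
                dimnames = list(NULL, colnames(tab)[-1]))
    if (any(!is.finite(m)) || any(m < 0) || any(m != trunc(m))) {
      stop("non-integer count in dense table")
    }
    raw_counts(m, gene_ids = ids, cell_ids = colnames(tab)[-1])
  }
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: writes either the 10x-style triplet layout
#' (`matrix.mtx` + `genes.tsv` + `barcodes.tsv`) into a directory, or a
#' dense tab-separated table. Integer counts round-trip exactly.
#'
#' @param m A [raw_counts] object.
#' @param path Output directory (`mtx_triplet`) or file path (`dense_table`).
#' @param format `"mtx_triplet"` or `"dense_table"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, format = c("mtx_triplet", "dense_table")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "raw_counts"))
  if (format == "mtx_triplet") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
    writeLines(m$gene_ids, file.path(path, "genes.tsv"))
    writeLines(m$cell_ids, file.path(path, "barcodes.tsv"))
  } else {
    dense <- as.matrix(m$counts)
    df <- data.frame(gene = m$gene_ids, dense, check.names = FALSE)
    colnames(df) <- c("gene", m$cell_ids)
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Cell-level quality-control thresholds
#'
#' Cells are retained when they have at least `min_genes` detected genes,
#' at least `min_umi` total UMI, and a mitochondrial UMI fraction of at most
#' `max_mito_fraction`. Defaults are the conventional droplet scRNA-seq
#' cutoffs used with PBMC-scale data: 500 genes, 1,500 UMI, 10% mitochondrial
#' reads. Mitochondrial genes are identified either by an explicit id set or
#' by id prefix (default `"MT-"`/`"mt-"`).
#'
#' @param min_genes Minimum number of detected (count > 0) genes per cell.
#' @param min_umi Minimum total UMI per cell.
#' @param max_mito_fraction Maximum mitochondrial UMI fraction, in \[0, 1\].
#' @param mito_genes Optional explicit character vector of mitochondrial
#'   gene ids; overrides prefix matching when non-`NULL`.
#' @param mito_prefix Character vector of id prefixes marking mitochondrial
#'   genes when `mito_genes` is `NULL`.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500, min_umi = 1500,
                          max_mito_fraction = 0.1, mito_genes = NULL,
                          mito_prefix = c("MT-", "mt-")) {
  stopifnot(min_genes >= 0, min_umi >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes = as.integer(min_genes),
                 min_umi = as.integer(min_umi),
                 max_mito_fraction = max_mito_fraction,
                 mito_genes = mito_genes, mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

mito_gene_mask <- function(gene_ids, t) {
  if (!is.null(t$mito_genes)) {
    absent <- setdiff(t$mito_genes, gene_ids)
    if (length(absent)) {
      warning("mitochondrial genes absent from matrix: ",
              paste(head(absent, 5), collapse = ", "),
              if (length(absent) > 5) ", ..." else "")
    }
    gene_ids %in% t$mito_genes
  } else {
    Reduce(`|`, lapply(t$mito_prefix, function(p) startsWith(gene_ids, p)))
  }
}

#' Filter low-quality cells
#'
#' Applies the three cell-level predicates of [qc_thresholds()] and returns
#' the retained submatrix together with a per-cell report. The gene set is
#' never changed; genes left with zero total count across retained cells are
#' flagged in the `zero_genes` element (downstream inverse-cell-frequency
#' handles `n_i = 0`).
#'
#' @param m A [raw_counts] object.
#' @param thresholds A [qc_thresholds] object.
#' @return A list of class `qc_result` with elements `counts` (filtered
#'   [raw_counts]), `report` (tibble: `cell_id`, `n_genes`, `n_umi`,
#'   `mito_fraction`, `pass`), and `zero_genes` (character vector).
#' @export
qc_filter <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "raw_counts"), inherits(thresholds, "qc_thresholds"))
  cm <- m$counts
  n_umi <- Matrix::colSums(cm)
  n_genes <- Matrix::colSums(cm > 0)
  mito <- mito_gene_mask(m$gene_ids, thresholds)
  mito_umi <- if (any(mito)) Matrix::colSums(cm[mito, , drop = FALSE]) else
    rep(0, ncol(cm))
  mito_frac <- ifelse(n_umi > 0, mito_umi / n_umi, 0)
  pass <- n_genes >= thresholds$min_genes &
    n_umi >= thresholds$min_umi &
    mito_frac <= thresholds$max_mito_fraction
  report <- tibble::tibble(cell_id = m$cell_ids,
                           n_genes = as.integer(unname(n_genes)),
                           n_umi = as.integer(unname(n_umi)),
                           mito_fraction = as.numeric(unname(mito_frac)),
                           pass = unname(pass))
  if (!any(pass)) {
    stop("no cells retained: every cell failed the QC thresholds")
  }
  kept <- raw_counts(cm[, pass, drop = FALSE], m$gene_ids, m$cell_ids[pass])
  zero <- m$gene_ids[Matrix::rowSums(kept$counts) == 0]
  structure(list(counts = kept, report = report, zero_genes = zero),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %d / %d cells retained, %d all-zero genes flagged\n",
              sum(x$report$pass), nrow(x$report), length(x$zero_genes)))
  invisible(x)
}

#' @rdname qc_filter
#' @param x A `qc_result`.
#' @param ... Unused.
#' @export
tidy.qc_result <- function(x, ...) x$report

#' Write a per-cell QC report
#'
#' @param x A `qc_result` from [qc_filter()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(x, path) {
  stopifnot(inherits(x, "qc_result"))
  readr::write_tsv(x$report, path, progress = FALSE)
  invisible(path)
}
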
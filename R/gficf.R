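#' Gene frequency: per-cell sum-to-one normalization
#'
#' Divides each cell's counts by the cell's total UMI, the direct analogue
#' of term frequency in text mining. Each column of the result sums to one;
#' the sparsity pattern is unchanged.
#'
#' @param m A [raw_counts] object.
#' @return A sparse `dgCMatrix` (genes x cells) of gene frequencies.
#' @export
gene_frequency <- function(m) {
  stopifnot(inherits(m, "raw_counts"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) {
    stop("all-zero cell column(s): ",
         paste(head(m$cell_ids[tot == 0], 5), collapse = ", "))
  }
  gf <- m$counts %*% Matrix::Diagonal(x = 1 / tot)
  gf <- as(as(gf, "CsparseMatrix"), "generalMatrix")
  dimnames(gf) <- list(m$gene_ids, m$cell_ids)
  gf
}

#' Inverse cell frequency
#'
#' Computes, for every gene, `icf_i = log(N / (n_i + 1))` where `N` is the
#' number of cells and `n_i` the number of cells in which gene `i` is
#' detected (count > 0). Genes expressed in few cells receive high weight;
#' ubiquitous genes receive weight near (or, when `n_i = N`, below) zero.
#'
#' The add-one smoothing sits in the denominator by default. The variant
#' `smoothing = "add_one_outside"` computes `log(N / n_i + 1)` instead
#' (for `n_i = 0` that limit is `Inf`; such genes carry no counts, so the
#' weight is never applied to a nonzero entry).
#'
#' @param m A [raw_counts] object.
#' @param smoothing `"add_one_denominator"` (default) or
#'   `"add_one_outside"`.
#' @param log_base Base of the logarithm (natural log by default; the choice
#'   cancels under the final L2 normalization).
#' @return A tibble with columns `gene_id`, `n_cells_expressing`, `icf`.
#' @export
inverse_cell_frequency <- function(m,
                                   smoothing = c("add_one_denominator",
                                                 "add_one_outside"),
                                   log_base = exp(1)) {
  stopifnot(inherits(m, "raw_counts"))
  smoothing <- match.arg(smoothing)
  N <- ncol(m$counts)
  stopifnot(N >= 1)
  n_i <- Matrix::rowSums(m$counts > 0)
  icf <- switch(smoothing,
    add_one_denominator = log(N / (n_i + 1), base = log_base),
    add_one_outside     = log(N / n_i + 1, base = log_base))
  tibble::tibble(gene_id = m$gene_ids,
                 n_cells_expressing = as.integer(n_i),
                 icf = as.numeric(icf))
}

#' Gene frequency-inverse cell frequency transform
#'
#' The core normalization: each entry becomes
#' `GF[i,j] * ICF[i]` and each cell column is then rescaled to unit
#' Euclidean norm (L2 normalization), so residual depth differences cancel.
#'
#' Genes detected in every cell get a negative ICF under the default
#' smoothing (`log(N/(N+1)) < 0`). Because a negative "relevance" weight
#' inverts the meaning of the score, the default policy clamps ICF at zero
#' and flags the affected genes; set `allow_negative_icf = TRUE` to keep the
#' literal formula value.
#'
#' @param m A [raw_counts] object; must contain no all-zero cells (run
#'   [qc_filter()] first with `min_umi >= 1`).
#' @param smoothing,log_base Passed to [inverse_cell_frequency()].
#' @param allow_negative_icf Keep negative ICF values instead of clamping
#'   them at zero.
#' @return An object of class `gficf_matrix`: list with `weights` (sparse
#'   genes x cells, unit-L2 columns), `gene_ids`, `cell_ids`, `icf` (tibble
#'   from [inverse_cell_frequency()], with a `clamped` flag column), and
#'   `params`.
#' @export
gficf_transform <- function(m,
                            smoothing = c("add_one_denominator",
                                          "add_one_outside"),
                            log_base = exp(1),
                            allow_negative_icf = FALSE) {
  smoothing <- match.arg(smoothing)
  gf <- gene_frequency(m)
  icf_tbl <- inverse_cell_frequency(m, smoothing = smoothing,
                                    log_base = log_base)
  icf <- icf_tbl$icf
  clamped <- rep(FALSE, length(icf))
  if (!allow_negative_icf && any(icf < 0)) {
    clamped <- icf < 0
    icf[clamped] <- 0
  }
  icf_tbl$clamped <- clamped
  # row-scaling of a sparse matrix touches stored entries only, so an
  # infinite ICF on an unexpressed gene (add_one_outside, n_i = 0) never
  # multiplies a structural zero
  w <- Matrix::Diagonal(x = icf) %*% gf
  w <- as(as(w, "CsparseMatrix"), "generalMatrix")
  w <- Matrix::drop0(w)
  norms <- sqrt(Matrix::colSums(w^2))
  if (any(norms == 0)) {
    stop("degenerate cell(s) with all-zero gf-icf weights ",
         "(every expressed gene has ICF 0): ",
         paste(head(m$cell_ids[norms == 0], 5), collapse = ", "))
  }
  w <- w %*% Matrix::Diagonal(x = 1 / norms)
  w <- as(as(w, "CsparseMatrix"), "generalMatrix")
  dimnames(w) <- list(m$gene_ids, m$cell_ids)
  structure(list(weights = w, gene_ids = m$gene_ids, cell_ids = m$cell_ids,
                 icf = icf_tbl,
                 params = list(smoothing = smoothing, log_base = log_base,
                               allow_negative_icf = allow_negative_icf,
                               n_cells = ncol(m$counts))),
            class = "gficf_matrix")
}

#' @export
print.gficf_matrix <- function(x, ...) {
  cat(sprintf(
    "<gficf_matrix> %d genes x %d cells (smoothing: %s, %d ICF values clamped)\n",
    nrow(x$weights), ncol(x$weights), x$params$smoothing,
    sum(x$icf$clamped)))
  invisible(x)
}

#' @rdname gficf_transform
#' @param x A `gficf_matrix`.
#' @param ... Unused.
#' @return `tidy()`: the per-gene ICF tibble (`gene_id`,
#'   `n_cells_expressing`, `icf`, `clamped`).
#' @export
tidy.gficf_matrix <- function(x, ...) x$icf

#' @rdname gficf_transform
#' @export
glance.gficf_matrix <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$weights), n_cells = ncol(x$weights),
                 smoothing = x$params$smoothing,
                 n_clamped = sum(x$icf$clamped),
                 sparsity = 1 - Matrix::nnzero(x$weights) /
                   (as.numeric(nrow(x$weights)) * ncol(x$weights)))
}

#' Write gf-icf weights to disk
#'
#' Writes the real-valued weights in Matrix Market format with sidecar gene
#' and cell lists plus a per-gene TSV of `n_cells_expressing` and `icf`.
#'
#' @param g A `gficf_matrix`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_gficf <- function(g, dir) {
  stopifnot(inherits(g, "gficf_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(g$weights, file.path(dir, "gficf.mtx"))
  writeLines(g$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(g$cell_ids, file.path(dir, "barcodes.tsv"))
  readr::write_tsv(g$icf, file.path(dir, "icf.tsv"), progress = FALSE)
  invisible(dir)
}

#' Library-size log normalization (comparison baseline)
#'
#' Plain `log1p(count / depth * scale)` normalization, provided only as a
#' baseline against which the gf-icf weighting can be compared in
#' evaluation; it is not part of the gf-icf pipeline itself.
#'
#' @param m A [raw_counts] object.
#' @param scale Scale factor (default 1e4).
#' @return A sparse genes x cells matrix of log-normalized values.
#' @export
log_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "raw_counts"))
  tot <- Matrix::colSums(m$counts)
  if (any(tot == 0)) stop("all-zero cell column(s)")
  out <- m$counts %*% Matrix::Diagonal(x = scale / tot)
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m$counts)
  out
}
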